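#' Specify ground-truth kinetics for a synthetic biodistribution study
#'
#' Defines, per source region of an animal phantom, a sum-of-exponentials
#' ground truth for the decay-uncorrected fraction of administered activity,
#' `a_r(t) = sum_psi c_psi exp(-(lambda_b_psi + lambda_p) t)`, plus the
#' study design: measurement schedule, replicates per time point, animal
#' body-mass distribution and a multiplicative log-normal measurement noise
#' model with fixed coefficient of variation (counting measurements are
#' positive with roughly constant CV).  The total body is the sum of all
#' listed regions, so the zero-time amplitudes must sum to at most 1.
#'
#' @param regions Named list; each element a list/data.frame with vectors
#'   `c` (amplitudes >= 0) and `lambda_b` (biological rates, 1/h).  Include
#'   a remainder region (e.g. `"Rest"`) so the regions jointly account for
#'   the whole body.
#' @param nuclide `predose_nuclide`.
#' @param animal `predose_phantom` of the animal species; region masses
#'   (scaled to each sampled body mass) convert ground-truth fractions into
#'   measured %IA/g.
#' @param schedule `predose_schedule` of measurement times.
#' @param replicates Animals per time point.
#' @param body_mass_mean_g,body_mass_sd_g Animal body-mass distribution.
#' @param cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise (0 = noiseless).
#' @param fu Urinary fractions per total-body clearance component (optional,
#'   for bladder-model ground truth).
#' @param voiding_interval_h Bladder voiding interval (optional).
#' @return An object of class `predose_kinetic_spec`.
#' @export
kinetic_spec <- function(regions, nuclide, animal, schedule,
                         replicates = 3L, body_mass_mean_g = 25,
                         body_mass_sd_g = 2, cv = 0.05,
                         fu = NULL, voiding_interval_h = NULL) {
  stopifnot(inherits(nuclide, "predose_nuclide"),
            inherits(animal, "predose_phantom"),
            inherits(schedule, "predose_schedule"))
  if (is.null(names(regions)) || any(names(regions) == "")) {
    pd_stop("regions must be a named list")
  }
  a0 <- 0
  for (r in names(regions)) {
    k <- regions[[r]]
    if (is.null(k$c) || is.null(k$lambda_b) || length(k$c) != length(k$lambda_b)) {
      pd_stop(sprintf("region '%s' needs equal-length vectors c and lambda_b", r))
    }
    if (any(k$c < 0)) pd_stop(sprintf("region '%s': amplitudes must be >= 0", r))
    # "Rest" is the unobserved remainder: no phantom region, never assayed
    # directly; it reaches the dataset through the carcass and total body
    if (r != "Rest" && !r %in% animal$regions$region) {
      pd_stop(sprintf("kinetic region '%s' is not defined in the animal phantom", r))
    }
    a0 <- a0 + sum(k$c)
  }
  if (a0 > 1 + 1e-9) {
    pd_stop(sprintf("zero-time amplitudes sum to %.6g > 1: infeasible administered-activity balance", a0))
  }
  if (cv < 0) pd_stop("noise CV must be >= 0")
  if (replicates < 1) pd_stop("need at least 1 replicate per time point")
  structure(list(regions = regions, nuclide = nuclide, animal = animal,
                 schedule = schedule, replicates = as.integer(replicates),
                 body_mass_mean_g = body_mass_mean_g,
                 body_mass_sd_g = body_mass_sd_g, cv = cv,
                 fu = fu, voiding_interval_h = voiding_interval_h),
            class = "predose_kinetic_spec")
}

# ground-truth decay-uncorrected fraction for one region spec
truth_a <- function(k, lambda_p, t) {
  as.vector(exp(-outer(t, k$lambda_b + lambda_p)) %*% k$c)
}

#' Simulate a biodistribution study with known ground truth
#'
#' Realizes the kinetic specification as an ex vivo counting dataset:
#' per region, time point and replicate, the true decay-uncorrected fraction
#' is converted to decay-corrected %IA/g through the inverse of the
#' SUV transposition (`[%IA/g] = a e^{+lambda_p t} \cdot 100 / M(region)`,
#' with region masses scaled to each animal's sampled body mass) and
#' multiplied by mean-1 log-normal noise.  A carcass-style dataset
#' (carcass = whole body minus the other listed regions) and a whole-body
#' dose-calibrator ratio series are emitted consistently from the same
#' ground truth, together with the closed-form ground-truth TIACs for
#' recovery testing.
#'
#' @param spec A `predose_kinetic_spec`.
#' @param seed Integer seed; the same seed reproduces the tables bit-exactly
#'   and is recorded in the output.
#' @return List with elements `biodist` (measurement table in the
#'   [read_biodist()] layout, including `Carcass` rows), `ratios`
#'   (`time_h`, `reading` whole-body series including t = 0), `truth`
#'   (`data.frame` of ground-truth TIACs per region, total body included),
#'   `spec`, and `seed`.
#' @export
simulate_biodist <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "predose_kinetic_spec"))
  set.seed(seed)
  lp <- spec$nuclide$lambda_p
  times <- spec$schedule$times_h
  nrep <- spec$replicates
  animal <- spec$animal
  sdlog <- sqrt(log(1 + spec$cv^2))
  noise <- function(n) {
    if (spec$cv == 0) rep(1, n) else rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  regions <- names(spec$regions)
  # one animal cohort per time point (terminal ex vivo counting)
  masses <- matrix(pmax(rnorm(length(times) * nrep, spec$body_mass_mean_g,
                              spec$body_mass_sd_g),
                        0.2 * spec$body_mass_mean_g),
                   nrow = length(times))
  scale_mass <- function(region, body_mass) {
    region_mass(animal, region) * body_mass / animal$total_body_mass_g
  }
  rows <- list()
  a_tb <- rep(0, length(times))
  for (r in regions) {
    a_true <- truth_a(spec$regions[[r]], lp, times)
    a_tb <- a_tb + a_true
    if (r == "Rest") next  # unobserved remainder, surfaces via the carcass
    for (i in seq_along(times)) {
      for (j in seq_len(nrep)) {
        m_r <- scale_mass(r, masses[i, j])
        pct <- a_true[i] * exp(lp * times[i]) * 100 / m_r
        rows[[length(rows) + 1L]] <- data.frame(
          region = r, time_h = times[i], replicate = j,
          value = pct * noise(1), unit = "pct_ia_per_g",
          body_mass_g = masses[i, j])
      }
    }
  }
  # carcass = whole body minus all other listed regions; requires the animal
  # phantom to define a Carcass region covering the remainder mass
  if ("Carcass" %in% animal$regions$region && !"Carcass" %in% regions) {
    a_carc <- if ("Rest" %in% regions) truth_a(spec$regions[["Rest"]], lp, times)
              else rep(0, length(times))
    for (i in seq_along(times)) {
      for (j in seq_len(nrep)) {
        m_c <- scale_mass("Carcass", masses[i, j])
        pct <- a_carc[i] * exp(lp * times[i]) * 100 / m_c
        rows[[length(rows) + 1L]] <- data.frame(
          region = "Carcass", time_h = times[i], replicate = j,
          value = pct * noise(1), unit = "pct_ia_per_g",
          body_mass_g = masses[i, j])
      }
    }
  }
  biodist <- do.call(rbind, rows)
  # whole-body dose-calibrator route: reading ratio = a_TB(t)/a_TB(0)
  a_tb0 <- sum(vapply(spec$regions, function(k) sum(k$c), 0))
  ratio <- a_tb / a_tb0
  ratio_noise <- noise(length(times))
  ratios <- data.frame(time_h = c(0, times),
                       reading = c(1, ratio * ratio_noise))
  truth <- do.call(rbind, lapply(regions, function(r) {
    k <- spec$regions[[r]]
    data.frame(region = r, tiac_h = sum(k$c / (k$lambda_b + lp)))
  }))
  tb_tiac <- sum(vapply(spec$regions, function(k) sum(k$c / (k$lambda_b + lp)), 0))
  truth <- rbind(truth, data.frame(region = "Totalbody", tiac_h = tb_tiac))
  list(biodist = biodist, ratios = ratios, truth = truth, spec = spec,
       seed = seed)
}
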