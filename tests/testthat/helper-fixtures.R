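# Shared fixtures, built in code.

ext_file <- function(f) system.file("extdata", f, package = "predose")

toy_mouse <- function() load_phantom(ext_file("mouse_phantom.csv"), species = "mouse")
toy_human <- function() load_phantom(ext_file("human_phantom.csv"), species = "human")
toy_nuclide <- function() load_nuclide(ext_file("nuclide.csv"))
toy_svalues <- function(ph = toy_human()) {
  load_svalues(ext_file("svalues_human.csv"), ph, nuclide_name = "betagamma_toy")
}
toy_weights <- function() load_weights(ext_file("weights.csv"))

# nuclide with a chosen decay constant (1/h)
nuclide_lp <- function(lp, delta_np_J = 0) {
  radionuclide(sprintf("lp%g", lp), log(2) / lp, delta_np_J)
}

# mouse-to-mouse study whose total-body curve stays within the fitted model
# class: every region clears with rates drawn from the same pair, so organ
# and total-body curves are exactly bi-exponential
closed_loop_spec <- function(cv = 0, replicates = 3L, n_points = 5L) {
  nuc <- toy_nuclide()
  te <- effective_half_life(0.02, nuc)
  sch <- plan_empirical(n_points, te)
  kinetic_spec(
    regions = list(
      Liver   = list(c = c(0.15, 0.05), lambda_b = c(0.2, 0.02)),
      Kidneys = list(c = c(0.10, 0.02), lambda_b = c(0.2, 0.02)),
      Blood   = list(c = c(0.18, 0.02), lambda_b = c(0.2, 0.02)),
      Rest    = list(c = c(0.28, 0.20), lambda_b = c(0.2, 0.02))),
    nuclide = nuc, animal = toy_mouse(), schedule = sch,
    replicates = replicates, body_mass_mean_g = 25, body_mass_sd_g = 2,
    cv = cv, fu = c(0.6, 0.2), voiding_interval_h = 4)
}

# ground-truth TIAC of one kinetic region, closed form
truth_tiac <- function(spec, region) {
  k <- spec$regions[[region]]
  sum(k$c / (k$lambda_b + spec$nuclide$lambda_p))
}

# minimal hand-built fit object for exercising downstream TIAC operations
fake_fit <- function(c, lambda_b, lambda_p, region = "Totalbody") {
  structure(list(region = region, psi = length(c), c = c, lambda_b = lambda_b,
                 lambda_p = lambda_p, wrss = 0, dof = 1L, score = NA_real_,
                 converged = TRUE, vcov = NULL),
            class = "predose_fit")
}
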