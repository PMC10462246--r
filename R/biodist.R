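#' Convert %IA/g to SUV
#'
#' The standardized uptake value is the activity mass concentration,
#' decay-corrected to the time of administration, normalized to administered
#' activity per unit body mass: `SUV = [%IA/g] * M(body) / 100` with the body
#' mass in grams.  Under this mass convention SUV is dimensionless.
#'
#' @param pct Activity concentration in percent of administered activity per
#'   gram of tissue (decay-corrected).  Vectorized.
#' @param body_mass_g Subject total-body mass in grams (vectorized, recycled).
#' @return SUV values.
#' @seealso [pct_ia_per_g_from_suv()] for the exact inverse.
#' @export
suv_from_pct_ia_per_g <- function(pct, body_mass_g) {
  if (any(pct < 0, na.rm = TRUE)) pd_stop("%IA/g values must be >= 0")
  if (any(body_mass_g <= 0, na.rm = TRUE)) pd_stop("body mass must be > 0")
  pct * body_mass_g / 100
}

#' Convert SUV to %IA/g
#'
#' Exact inverse of [suv_from_pct_ia_per_g()].
#'
#' @param suv SUV values (>= 0).
#' @param body_mass_g Subject total-body mass in grams.
#' @return %IA/g values.
#' @export
pct_ia_per_g_from_suv <- function(suv, body_mass_g) {
  if (any(suv < 0, na.rm = TRUE)) pd_stop("SUV values must be >= 0")
  if (any(body_mass_g <= 0, na.rm = TRUE)) pd_stop("body mass must be > 0")
  suv * 100 / body_mass_g
}

#' Convert a volume concentration (%IA/mL) to a mass concentration (%IA/g)
#'
#' Tomographic image quantification yields volume concentrations; these must
#' be divided by tissue density to obtain mass concentrations.  Soft-tissue
#' density is conventionally taken as 1 g/mL.
#'
#' @param value Concentration in %IA/mL.
#' @param density_g_per_ml Tissue density in g/mL (default 1).
#' @return Concentration in %IA/g.
#' @export
concentration_from_volume <- function(value, density_g_per_ml = 1) {
  if (any(density_g_per_ml <= 0)) pd_stop("tissue density must be > 0")
  value / density_g_per_ml
}

#' Read a biodistribution table from CSV
#'
#' Columns `region,time_h,replicate,value,unit,body_mass_g` with
#' `unit` one of `pct_ia_per_g`, `suv`, `pct_ia_per_ml`.  Values are assumed
#' decay-corrected to the time of administration (the definition of %IA/g and
#' SUV).
#'
#' @param path Path to the CSV file.
#' @return A validated `data.frame`.
#' @export
read_biodist <- function(path) {
  if (!file.exists(path)) pd_format_stop(sprintf("no such file: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("region", "time_h", "replicate", "value", "unit", "body_mass_g")
  if (!all(req %in% names(df))) {
    pd_format_stop(sprintf("biodistribution file lacks column(s): %s",
                           paste(setdiff(req, names(df)), collapse = ", ")))
  }
  validate_biodist(df)
}

validate_biodist <- function(df) {
  ok_units <- c("pct_ia_per_g", "suv", "pct_ia_per_ml")
  if (!all(df$unit %in% ok_units)) {
    pd_stop(sprintf("unknown unit(s): %s (allowed: %s)",
                    paste(setdiff(unique(df$unit), ok_units), collapse = ", "),
                    paste(ok_units, collapse = ", ")))
  }
  if (any(df$time_h < 0)) pd_stop("measurement times must be >= 0")
  if (any(df$value < 0)) pd_stop("activity concentrations must be >= 0")
  if (any(df$body_mass_g <= 0)) pd_stop("animal body masses must be > 0")
  df
}

# per-row conversion to SUV; density may be a single number or a named
# per-region vector of overrides
row_suv <- function(df, density_g_per_ml = 1) {
  dens <- rep(1, nrow(df))
  if (length(density_g_per_ml) == 1L && is.null(names(density_g_per_ml))) {
    dens[] <- density_g_per_ml
  } else {
    hit <- match(df$region, names(density_g_per_ml))
    dens[!is.na(hit)] <- density_g_per_ml[hit[!is.na(hit)]]
  }
  v <- df$value
  v[df$unit == "pct_ia_per_ml"] <-
    concentration_from_volume(v[df$unit == "pct_ia_per_ml"],
                              dens[df$unit == "pct_ia_per_ml"])
  is_pct <- df$unit %in% c("pct_ia_per_g", "pct_ia_per_ml")
  out <- v
  out[is_pct] <- suv_from_pct_ia_per_g(v[is_pct], df$body_mass_g[is_pct])
  out
}

#' Construct a per-region concentration series
#'
#' @param region Region name.
#' @param time_h Strictly increasing measurement times (h post-administration).
#' @param mean_suv Mean SUV at each time point.
#' @param sd_suv Sample standard deviation of SUV at each time point (0 when
#'   `n = 1`).
#' @param n Number of replicates at each time point.
#' @param meta Optional list of provenance metadata.
#' @return An object of class `predose_conc_series`.
#' @export
concentration_series <- function(region, time_h, mean_suv, sd_suv = rep(0, length(time_h)),
                                 n = rep(1L, length(time_h)), meta = list()) {
  if (length(time_h) == 0L) pd_stop("concentration series needs at least one time point")
  if (is.unsorted(time_h, strictly = TRUE)) pd_stop("times must be strictly increasing")
  if (length(mean_suv) != length(time_h) || length(sd_suv) != length(time_h) ||
      length(n) != length(time_h)) {
    pd_stop("time_h, mean_suv, sd_suv and n must have equal length")
  }
  if (any(n < 1)) pd_stop("each time point needs n >= 1 replicates")
  if (any(sd_suv < 0)) pd_stop("SDs must be >= 0")
  if (any(sd_suv[n == 1] != 0)) pd_stop("SD must be 0 where n = 1")
  structure(list(region = as.character(region), time_h = as.numeric(time_h),
                 mean_suv = as.numeric(mean_suv), sd_suv = as.numeric(sd_suv),
                 n = as.integer(n), meta = meta),
            class = "predose_conc_series")
}

#' @export
print.predose_conc_series <- function(x, ...) {
  cat(sprintf("<SUV series '%s', %d time points%s>\n", x$region, length(x$time_h),
              if (isTRUE(x$meta$mean_mass)) ", population-mean-mass approximation" else ""))
  print(data.frame(time_h = x$time_h, mean_suv = x$mean_suv,
                   sd_suv = x$sd_suv, n = x$n), row.names = FALSE)
  invisible(x)
}

#' Aggregate replicate measurements into a mean-SUV series
#'
#' Converts each measurement to SUV and computes, per time point, the
#' arithmetic mean and sample standard deviation (n - 1 denominator) across
#' replicates.  By default each animal's SUV uses its own body mass; setting
#' `use_mean_mass = TRUE` applies the population-mean-body-mass approximation
#' instead (appropriate when animal body masses are reasonably consistent),
#' which is flagged in the output metadata.
#'
#' @param measurements `data.frame` in the [read_biodist()] layout, restricted
#'   to a single region.
#' @param use_mean_mass Use the population mean body mass for all animals.
#' @param density_g_per_ml Tissue density for `pct_ia_per_ml` rows: a single
#'   number or a named per-region vector (default 1).
#' @return A `predose_conc_series`.
#' @export
aggregate_suv <- function(measurements, use_mean_mass = FALSE, density_g_per_ml = 1) {
  df <- validate_biodist(measurements)
  if (!nrow(df)) pd_stop("no measurements supplied")
  regs <- unique(df$region)
  if (length(regs) != 1L) {
    pd_stop(sprintf("aggregate_suv() expects one region, got: %s",
                    paste(regs, collapse = ", ")))
  }
  if (use_mean_mass) df$body_mass_g <- mean(df$body_mass_g)
  suv <- row_suv(df, density_g_per_ml)
  times <- sort(unique(df$time_h))
  m <- vapply(times, function(ti) mean(suv[df$time_h == ti]), 0)
  s <- vapply(times, function(ti) {
    v <- suv[df$time_h == ti]
    if (length(v) > 1L) sd(v) else 0
  }, 0)
  nn <- vapply(times, function(ti) sum(df$time_h == ti), 0L)
  concentration_series(regs, times, m, s, nn,
                       meta = list(mean_mass = use_mean_mass,
                                   body_mass_mean_g = mean(df$body_mass_g)))
}

#' Assemble a total-body SUV series from carcass + excised-organ series
#'
#' For ex vivo counting studies where organs are excised and the remaining
#' carcass is counted, the total-body concentration is the mass-weighted sum
#' of the carcass and the excised regions,
#' `SUV(TB) = (SUV(carcass) M(carcass) + sum SUV(rS) M(rS)) / M(TB)`,
#' with all masses taken from the phantom (the masses of the harvested
#' samples themselves need not be known).  Regions must not be double
#' counted: each excised region may appear once and the carcass must exclude
#' them.
#'
#' @param carcass `predose_conc_series` for the carcass.
#' @param excised List of `predose_conc_series` for the excised regions.
#' @param phantom `predose_phantom` providing the region masses; must define
#'   a region matching the carcass series name.
#' @param mass_tol Relative tolerance for the carcass + excised = total-body
#'   mass audit (default 0.5%); a mismatch warns.
#' @return A `predose_conc_series` for region `"Totalbody"`.  Replicate SDs
#'   are propagated as a mass-weighted linear combination of independent
#'   terms.
#' @export
total_body_from_carcass <- function(carcass, excised = list(), phantom,
                                    mass_tol = 0.005) {
  stopifnot(inherits(carcass, "predose_conc_series"),
            inherits(phantom, "predose_phantom"))
  if (inherits(excised, "predose_conc_series")) excised <- list(excised)
  ex_regions <- vapply(excised, function(s) s$region, "")
  if (anyDuplicated(ex_regions)) {
    pd_stop(sprintf("excised region(s) listed more than once: %s",
                    paste(unique(ex_regions[duplicated(ex_regions)]), collapse = ", ")))
  }
  if (carcass$region %in% ex_regions) {
    pd_stop("carcass region also listed among excised regions")
  }
  m_tb <- phantom$total_body_mass_g
  m_c <- region_mass(phantom, carcass$region)
  m_ex <- vapply(ex_regions, function(r) region_mass(phantom, r), 0)
  if (abs((m_c + sum(m_ex)) - m_tb) > mass_tol * m_tb) {
    pd_warn(sprintf("carcass (%.4g g) + excised (%.4g g) masses differ from total body (%.4g g) by more than %.2g%%",
                    m_c, sum(m_ex), m_tb, 100 * mass_tol),
            class = "predose_mass_mismatch")
  }
  for (s in excised) {
    if (!identical(s$time_h, carcass$time_h)) {
      pd_stop(sprintf("time grid of excised region '%s' differs from the carcass grid",
                      s$region))
    }
  }
  w_c <- m_c / m_tb
  w_ex <- m_ex / m_tb
  mean_tb <- carcass$mean_suv * w_c
  var_tb <- (carcass$sd_suv * w_c)^2
  for (k in seq_along(excised)) {
    mean_tb <- mean_tb + excised[[k]]$mean_suv * w_ex[k]
    var_tb <- var_tb + (excised[[k]]$sd_suv * w_ex[k])^2
  }
  n_min <- carcass$n
  for (s in excised) n_min <- pmin(n_min, s$n)
  sd_tb <- sqrt(var_tb)
  sd_tb[n_min == 1] <- 0
  concentration_series("Totalbody", carcass$time_h, mean_tb, sd_tb, n_min,
                       meta = list(route = "carcass",
                                   carcass_region = carcass$region,
                                   excised = ex_regions))
}

#' Read whole-body dose-calibrator readings from CSV
#'
#' Columns `time_h,reading`.  The reading at time 0 corresponds to 100% of
#' the administered activity; later readings are not decay-corrected.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` with columns `time_h`, `reading`.
#' @export
read_wholebody_ratios <- function(path) {
  if (!file.exists(path)) pd_format_stop(sprintf("no such file: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time_h", "reading") %in% names(df))) {
    pd_format_stop("whole-body ratio file needs columns time_h,reading")
  }
  df[order(df$time_h), , drop = FALSE]
}

#' Total-body activity fractions from whole-body reading ratios
#'
#' Dose-calibrator readings of the intact animal, divided by the reading
#' immediately post-administration, give the fraction of administered
#' activity remaining in the body.  Because the readings are physical
#' measurements they are already decay-uncorrected, so the ratios are used
#' directly as `a(Totalbody, Ti)` with no further decay factor.
#'
#' @param ratios `data.frame` with columns `time_h`, `reading` including a
#'   time-0 row.
#' @return A `predose_tas` (time-activity series) for region `"Totalbody"`.
#'   The leading time-0 point (ratio 1) is retained.
#' @export
total_body_from_ratios <- function(ratios) {
  if (!nrow(ratios)) pd_stop("empty whole-body reading series")
  ratios <- ratios[order(ratios$time_h), , drop = FALSE]
  i0 <- which(ratios$time_h == 0)
  if (!length(i0)) pd_stop("whole-body ratio series requires a time-0 reading (A_T0)")
  a <- ratios$reading / ratios$reading[i0[1]]
  if (any(a[ratios$time_h > 0] > 1 + 1e-9)) {
    pd_warn("whole-body fraction exceeds 1 after administration; value retained but physically inconsistent",
            class = "predose_fraction_gt_one")
  }
  time_activity_series("Totalbody", ratios$time_h, a, sd = rep(0, length(a)),
                       provenance = "dose-calibrator whole-body ratios")
}
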