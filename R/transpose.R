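#' Construct a time-activity series
#'
#' Holds decay-uncorrected fractions of administered activity `a(rS, Ti)` for
#' one phantom source region — the quantity that is integrated into the TIAC.
#'
#' @param region Phantom source-region name.
#' @param time_h Strictly increasing times post-administration (h).
#' @param a Fraction of administered activity at each time (dimensionless,
#'   NOT decay-corrected, >= 0).
#' @param sd Propagated standard deviation per point (>= 0).
#' @param provenance Free-text label recording how the series was derived
#'   (e.g. measured-region to phantom-region mapping).
#' @return An object of class `predose_tas`.
#' @export
time_activity_series <- function(region, time_h, a, sd = rep(0, length(a)),
                                 provenance = NA_character_) {
  if (!length(time_h)) pd_stop("time-activity series needs at least one point")
  if (is.unsorted(time_h, strictly = TRUE)) pd_stop("times must be strictly increasing")
  if (length(a) != length(time_h) || length(sd) != length(time_h)) {
    pd_stop("time_h, a and sd must have equal length")
  }
  if (any(a < 0)) pd_stop("activity fractions must be >= 0")
  if (any(sd < 0)) pd_stop("SDs must be >= 0")
  structure(list(region = as.character(region), time_h = as.numeric(time_h),
                 a = as.numeric(a), sd = as.numeric(sd),
                 provenance = as.character(provenance)),
            class = "predose_tas")
}

#' @export
print.predose_tas <- function(x, ...) {
  cat(sprintf("<time-activity series '%s' (%s), %d points>\n",
              x$region, x$provenance, length(x$time_h)))
  print(data.frame(time_h = x$time_h, a = signif(x$a, 6), sd = signif(x$sd, 6)),
        row.names = FALSE)
  invisible(x)
}

#' Transpose an SUV series onto a phantom source region
#'
#' Under the first-order cross-species assumption that the body-mass
#' normalized SUV is equivalent among species and the phantoms representing
#' them, the decay-uncorrected fraction of administered activity in phantom
#' source region rS is
#' \deqn{a(rS, T_i) = \overline{SUV}(rS)_i \,
#'   \frac{M(rS)}{M(Totalbody)} \, e^{-\lambda_p T_i}}
#' where the masses are the phantom's (inclusive of regional blood) and the
#' exponential negates the decay correction inherent in the SUV definition.
#' Same-species mapping (e.g. mouse data onto a mouse phantom) uses the
#' identical path.
#'
#' @param series `predose_conc_series` of mean SUV for a measured region.
#' @param phantom Destination `predose_phantom`.
#' @param nuclide `predose_nuclide` supplying the physical decay constant.
#' @param phantom_region Name of the phantom source region to populate;
#'   defaults to the series' own region name.
#' @return A `predose_tas`; SDs are scaled by the same mass-ratio/decay
#'   factor as the means.
#' @export
transpose_region <- function(series, phantom, nuclide,
                             phantom_region = series$region) {
  stopifnot(inherits(series, "predose_conc_series"),
            inherits(phantom, "predose_phantom"),
            inherits(nuclide, "predose_nuclide"))
  i <- match(phantom_region, phantom$regions$region)
  if (is.na(i)) {
    pd_stop(sprintf("phantom '%s' has no region '%s'", phantom$name, phantom_region))
  }
  if (!phantom$regions$is_source[i]) {
    pd_warn(sprintf("phantom region '%s' is not flagged source-capable", phantom_region),
            class = "predose_not_source")
  }
  f <- phantom$regions$mass_g[i] / phantom$total_body_mass_g
  dk <- exp(-nuclide$lambda_p * series$time_h)
  time_activity_series(phantom_region, series$time_h,
                       a = series$mean_suv * f * dk,
                       sd = series$sd_suv * f * dk,
                       provenance = sprintf("%s -> %s", series$region, phantom_region))
}

#' Red-marrow time-activity series from the blood surrogate
#'
#' Pure red-marrow samples are impractical to harvest from small animals;
#' the activity concentration of blood is conventionally (and usually
#' conservatively) taken as representative of the red marrow:
#' `a(Redmarrow, Ti) = SUV(Blood)_i * M(Redmarrow)/M(Totalbody) * exp(-lambda_p Ti)`.
#'
#' @param blood `predose_conc_series` of blood SUV.
#' @param phantom `predose_phantom` defining a red-marrow region.
#' @param nuclide `predose_nuclide`.
#' @param marrow_region Name of the phantom red-marrow region.
#' @return A `predose_tas` tagged as a blood surrogate.
#' @export
red_marrow_from_blood <- function(blood, phantom, nuclide,
                                  marrow_region = "Redmarrow") {
  if (!marrow_region %in% phantom$regions$region) {
    pd_stop(sprintf("phantom '%s' defines no red-marrow region '%s'",
                    phantom$name, marrow_region))
  }
  out <- transpose_region(blood, phantom, nuclide, marrow_region)
  out$provenance <- sprintf("%s (blood surrogate) -> %s", blood$region, marrow_region)
  out
}

#' Total-body activity fraction from a total-body SUV series
#'
#' For a whole-body region of interest (intact-animal counting or an image
#' ROI over the entire body) no mass ratio is needed, because the SUV of the
#' total body is already the decay-corrected fraction of administered
#' activity: `a(Totalbody, Ti) = SUV(Totalbody)_i * exp(-lambda_p Ti)`.
#'
#' @param series `predose_conc_series` for the total body.
#' @param nuclide `predose_nuclide`.
#' @return A `predose_tas` for region `"Totalbody"`.
#' @export
total_body_fraction <- function(series, nuclide) {
  stopifnot(inherits(series, "predose_conc_series"),
            inherits(nuclide, "predose_nuclide"))
  dk <- exp(-nuclide$lambda_p * series$time_h)
  time_activity_series("Totalbody", series$time_h,
                       a = series$mean_suv * dk, sd = series$sd_suv * dk,
                       provenance = sprintf("%s -> Totalbody", series$region))
}

#' Re-apply the decay correction to a time-activity series
#'
#' Multiplies by `exp(+lambda_p t)`, exactly inverting the decay
#' un-correction applied during transposition.  Useful for audits.
#'
#' @param tas A `predose_tas`.
#' @param nuclide `predose_nuclide`.
#' @return A `predose_tas` on the decay-corrected scale.
#' @export
decay_correct <- function(tas, nuclide) {
  stopifnot(inherits(tas, "predose_tas"), inherits(nuclide, "predose_nuclide"))
  dk <- exp(nuclide$lambda_p * tas$time_h)
  time_activity_series(tas$region, tas$time_h, tas$a * dk, tas$sd * dk,
                       provenance = paste(tas$provenance, "(decay-corrected)"))
}

#' Audit mass conservation across transposed source regions
#'
#' At every time point shared by all supplied series the summed fractions of
#' administered activity over disjoint source regions cannot exceed 1 (plus
#' measurement uncertainty).  Violations beyond `1 + 2 * SD(sum)` are
#' reported with the offending regions.
#'
#' @param tas_list List of `predose_tas` over disjoint regions.
#' @return Invisibly, a `data.frame` with columns `time_h`, `total_a`,
#'   `sd_sum`, `ok`.  Warns on violations.
#' @export
audit_mass_balance <- function(tas_list) {
  stopifnot(length(tas_list) >= 1, all(vapply(tas_list, inherits, TRUE, "predose_tas")))
  shared <- Reduce(intersect, lapply(tas_list, function(s) s$time_h))
  if (!length(shared)) {
    pd_warn("no time points shared by all series; mass-balance audit skipped",
            class = "predose_audit_skipped")
    return(invisible(data.frame(time_h = numeric(), total_a = numeric(),
                                sd_sum = numeric(), ok = logical())))
  }
  shared <- sort(shared)
  tot <- vapply(shared, function(ti) {
    sum(vapply(tas_list, function(s) s$a[match(ti, s$time_h)], 0))
  }, 0)
  sds <- vapply(shared, function(ti) {
    sqrt(sum(vapply(tas_list, function(s) s$sd[match(ti, s$time_h)], 0)^2))
  }, 0)
  ok <- tot <= 1 + 2 * sds + 1e-12
  if (any(!ok)) {
    regions <- paste(vapply(tas_list, function(s) s$region, ""), collapse = ", ")
    pd_warn(sprintf("summed activity fraction exceeds 1 at t = %s h over regions {%s}",
                    paste(signif(shared[!ok], 4), collapse = ", "), regions),
            class = "predose_mass_balance")
  }
  invisible(data.frame(time_h = shared, total_a = tot, sd_sum = sds, ok = ok))
}

#' Read a measured-region to phantom-region mapping table
#'
#' Columns `measured_region,phantom_region`.  Mapping is explicit — no fuzzy
#' matching; assay labels must be reconciled with the phantom's source-region
#' names before transposition.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` with the two columns.
#' @export
read_region_map <- function(path) {
  if (!file.exists(path)) pd_format_stop(sprintf("no such file: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("measured_region", "phantom_region") %in% names(df))) {
    pd_format_stop("region map needs columns measured_region,phantom_region")
  }
  df
}

#' Apply a region mapping to a biodistribution table
#'
#' Renames measured regions to their phantom counterparts.  Measured regions
#' without a mapping entry and without an identically named phantom region
#' are left unmapped (`NA`) with a message: their activity remains inside
#' the total body and is absorbed by the rest-of-body closure.
#'
#' @param measurements Biodistribution `data.frame` ([read_biodist()] layout).
#' @param map `data.frame` from [read_region_map()], or `NULL` for identity.
#' @param phantom Optional `predose_phantom` used to recognise identity
#'   mappings.
#' @return The table with a `phantom_region` column added.
#' @export
apply_region_map <- function(measurements, map = NULL, phantom = NULL) {
  out <- measurements
  out$phantom_region <- NA_character_
  if (!is.null(map)) {
    i <- match(out$region, map$measured_region)
    out$phantom_region[!is.na(i)] <- map$phantom_region[i[!is.na(i)]]
  }
  if (!is.null(phantom)) {
    ident <- is.na(out$phantom_region) & out$region %in% phantom$regions$region
    out$phantom_region[ident] <- out$region[ident]
  }
  un <- unique(out$region[is.na(out$phantom_region)])
  un <- setdiff(un, c("Totalbody", "Carcass"))
  if (length(un)) {
    message(sprintf("regions with no phantom counterpart routed to rest of body: %s",
                    paste(un, collapse = ", ")))
  }
  out
}
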