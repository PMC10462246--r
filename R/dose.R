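#' Absorbed dose coefficients from TIACs and S-values
#'
#' Within the MIRD schema the absorbed dose coefficient of a target region
#' is the S-value-weighted sum of the source-region TIACs:
#' \deqn{d(r_T) = \sum_{r_S} \tilde a(r_S) \, S(r_T \leftarrow r_S).}
#' TIACs are carried in hours throughout the package; the single hours ->
#' seconds conversion (factor 3600) happens here, so `d` is in Gy/Bq when
#' the S-values are in Gy/(Bq s).
#'
#' @param tiacs List of `predose_tiac` objects, or a named numeric vector of
#'   TIACs in hours (names = source regions).
#' @param svalues `predose_svalues` for the phantom + radionuclide.
#' @param phantom Optional `predose_phantom` (records the species so that
#'   [effective_dose()] can refuse non-human phantoms).
#' @param nuclide Optional `predose_nuclide`; its per-radiation-type dose
#'   fractions enable [equivalent_dose()] / [rbe_weighted_dose()] when the
#'   S-value table has no per-type breakdown.
#' @return An object of class `predose_dose_report`: per-target absorbed
#'   dose coefficients `$d` (Gy/Bq), the per-source `$contributions` matrix,
#'   and when available a per-radiation-type partition `$by_type`.
#' @export
absorbed_dose <- function(tiacs, svalues, phantom = NULL, nuclide = NULL) {
  stopifnot(inherits(svalues, "predose_svalues"))
  at <- as_tiac_vector(tiacs)
  unknown <- setdiff(names(at), svalues$sources)
  if (length(unknown)) {
    pd_stop(sprintf("TIAC supplied for region(s) with no S-value source column: %s",
                    paste(unknown, collapse = ", ")))
  }
  a_s <- at * 3600  # h -> s, exactly once
  contrib <- sweep(svalues$total[, names(at), drop = FALSE], 2L, a_s, `*`)
  d <- rowSums(contrib)
  by_type <- NULL
  if (!is.null(svalues$by_type)) {
    by_type <- vapply(svalues$by_type, function(m) {
      rowSums(sweep(m[, names(at), drop = FALSE], 2L, a_s, `*`))
    }, numeric(length(d)))
    if (is.null(dim(by_type))) by_type <- matrix(by_type, nrow = 1L,
                                                 dimnames = list(names(d), names(svalues$by_type)))
  }
  fractions <- if (!is.null(nuclide) && !is.null(nuclide$components)) {
    setNames(nuclide$components$dose_fraction, nuclide$components$radiation_type)
  }
  structure(list(phantom = svalues$phantom,
                 species = if (!is.null(phantom)) phantom$species else NA_character_,
                 nuclide = if (!is.null(nuclide)) nuclide$name else svalues$nuclide,
                 targets = names(d), d = d, contributions = contrib,
                 by_type = by_type, dose_fractions = fractions,
                 h = NULL, d_rbe = NULL, rbe_unit = NULL),
            class = "predose_dose_report")
}

as_tiac_vector <- function(tiacs) {
  if (is.numeric(tiacs)) {
    if (is.null(names(tiacs))) pd_stop("numeric TIAC vector must be named by source region")
    return(tiacs)
  }
  if (inherits(tiacs, "predose_tiac")) tiacs <- list(tiacs)
  stopifnot(all(vapply(tiacs, inherits, TRUE, "predose_tiac")))
  regs <- vapply(tiacs, function(x) x$region, "")
  if (anyDuplicated(regs)) {
    pd_stop(sprintf("duplicate TIAC region(s): %s",
                    paste(unique(regs[duplicated(regs)]), collapse = ", ")))
  }
  setNames(vapply(tiacs, function(x) x$tiac_h, 0), regs)
}

# per-radiation-type absorbed-dose partition for a report
dose_partition <- function(report) {
  if (!is.null(report$by_type)) return(report$by_type)
  if (!is.null(report$dose_fractions)) {
    return(outer(report$d, report$dose_fractions))
  }
  pd_stop("no per-radiation-type dose partition available: supply typed S-values or nuclide dose fractions")
}

#' Equivalent dose coefficients
#'
#' Weights the per-radiation-type absorbed dose partition by the radiation
#' weighting factors: `h(rT) = sum_R wR d_R(rT)`, in Sv/Bq.
#'
#' @param report `predose_dose_report` from [absorbed_dose()], carrying a
#'   per-radiation-type breakdown (typed S-values or nuclide dose fractions).
#' @param weights `predose_weights` providing `wR` for every radiation type
#'   present.
#' @return The report with `$h` (Sv/Bq) and a per-type equivalent-dose
#'   partition `$h_by_type` added.
#' @export
equivalent_dose <- function(report, weights) {
  stopifnot(inherits(report, "predose_dose_report"),
            inherits(weights, "predose_weights"))
  part <- dose_partition(report)
  types <- colnames(part)
  missing <- setdiff(types, names(weights$wR))
  if (length(missing)) {
    pd_stop(sprintf("no radiation weighting factor wR for type(s): %s",
                    paste(missing, collapse = ", ")))
  }
  h_by_type <- sweep(part, 2L, weights$wR[types], `*`)
  report$h <- rowSums(h_by_type)
  report$h_by_type <- h_by_type
  report
}

#' Effective dose coefficient
#'
#' The tissue-weighted, sex-averaged sum of equivalent dose coefficients:
#' \deqn{e = \sum_T w_T \frac{h_T^{Male} + h_T^{Female}}{2}.}
#' Effective dose is a stochastic-risk metric defined for reference humans
#' only; reports computed on a phantom whose recorded species is not human
#' are refused (animal studies should report absorbed or RBE-weighted dose).
#'
#' @param male,female `predose_dose_report`s carrying equivalent doses
#'   ([equivalent_dose()]) over the same target list.
#' @param weights `predose_weights` providing `wT`; every weighted tissue
#'   must be present in both reports.
#' @return An object of class `predose_effective_dose` with the scalar
#'   `$e_Sv_per_Bq` and a per-tissue `$contributions` table.
#' @export
effective_dose <- function(male, female, weights) {
  stopifnot(inherits(male, "predose_dose_report"),
            inherits(female, "predose_dose_report"),
            inherits(weights, "predose_weights"))
  for (rep_ in list(male, female)) {
    sp <- rep_$species
    if (!is.na(sp) && !grepl("human", sp, ignore.case = TRUE)) {
      pd_stop(sprintf("effective dose is defined for reference humans only; report uses a '%s' phantom — report absorbed or RBE-weighted dose instead",
                      sp))
    }
  }
  if (is.null(male$h) || is.null(female$h)) {
    pd_stop("both reports need equivalent doses; run equivalent_dose() first")
  }
  tissues <- names(weights$wT)
  missing <- setdiff(tissues, intersect(names(male$h), names(female$h)))
  if (length(missing)) {
    pd_stop(sprintf("tissue(s) in the wT table absent from a dose report: %s",
                    paste(missing, collapse = ", ")))
  }
  contrib <- weights$wT * (male$h[tissues] + female$h[tissues]) / 2
  structure(list(e_Sv_per_Bq = sum(contrib),
                 contributions = data.frame(tissue = tissues,
                                            wT = unname(weights$wT),
                                            h_male_Sv_per_Bq = unname(male$h[tissues]),
                                            h_female_Sv_per_Bq = unname(female$h[tissues]),
                                            contribution_Sv_per_Bq = unname(contrib))),
            class = "predose_effective_dose")
}

#' @export
print.predose_effective_dose <- function(x, ...) {
  cat(sprintf("<effective dose coefficient: %.6g Sv/Bq>\n", x$e_Sv_per_Bq))
  print(x$contributions, row.names = FALSE)
  invisible(x)
}

#' RBE-weighted dose coefficients
#'
#' For deterministic endpoints (therapy, tissue reactions) the absorbed dose
#' is weighted by a relative biological effectiveness factor per radiation
#' type: `d_RBE(rT) = sum_R RBE_R d_R(rT)`.  There is no consensus unit for
#' RBE-weighted dose; Gy, Gy-Eq and Sv are all in use, so the label is a
#' configuration choice.
#'
#' @param report `predose_dose_report` with a per-radiation-type breakdown.
#' @param rbe Named numeric vector, radiation type -> RBE factor (> 0).
#' @param unit Unit label for the weighted quantity.
#' @return The report with `$d_rbe` and `$rbe_unit` added.
#' @export
rbe_weighted_dose <- function(report, rbe, unit = c("Gy-Eq", "Gy", "Sv")) {
  stopifnot(inherits(report, "predose_dose_report"))
  unit <- match.arg(unit)
  if (any(rbe <= 0)) pd_stop("RBE factors must be > 0")
  part <- dose_partition(report)
  types <- colnames(part)
  missing <- setdiff(types, names(rbe))
  if (length(missing)) {
    pd_stop(sprintf("no RBE factor for radiation type(s): %s",
                    paste(missing, collapse = ", ")))
  }
  report$d_rbe <- rowSums(sweep(part, 2L, rbe[types], `*`))
  report$rbe_unit <- unit
  report
}

#' Self-dose sanity check
#'
#' For most radiopharmaceuticals the dominant dose contribution to a source
#' tissue comes from complete local absorption of its non-penetrating
#' emissions, so `d(self) ~ (a~ / M) * Delta_np` — TIAC per unit mass times
#' the mean non-penetrating energy per decay.  Comparing this first-principles
#' estimate with the computed coefficient catches mis-entered inputs;
#' agreement within about half an order of magnitude is expected.
#'
#' @param tiac `predose_tiac` (or TIAC in hours) for the region.
#' @param region_mass_g Region mass in grams.
#' @param nuclide `predose_nuclide` with `delta_np_J`.
#' @param reported_d Optional computed absorbed dose coefficient (Gy/Bq) to
#'   compare against.
#' @return List with `d_approx_Gy_per_Bq`, `ratio` (approx / reported, `NA`
#'   if no reported value), `flagged` (`TRUE` when |log10 ratio| > 0.5) and
#'   `skipped` (`TRUE` for a pure-photon emitter, `Delta_np = 0`).
#' @export
self_dose_check <- function(tiac, region_mass_g, nuclide, reported_d = NULL) {
  stopifnot(inherits(nuclide, "predose_nuclide"))
  a_h <- if (inherits(tiac, "predose_tiac")) tiac$tiac_h else pd_num1(tiac, "tiac")
  m <- pd_num1(region_mass_g, "region_mass_g")
  if (m <= 0) pd_stop("region mass must be > 0")
  if (nuclide$delta_np_J == 0) {
    message("Delta_np = 0 (pure-photon emitter); self-dose check skipped")
    return(list(d_approx_Gy_per_Bq = 0, ratio = NA_real_, flagged = FALSE,
                skipped = TRUE))
  }
  d_approx <- a_h * 3600 * nuclide$delta_np_J / (m / 1000)
  ratio <- if (!is.null(reported_d)) d_approx / reported_d else NA_real_
  flagged <- is.finite(ratio) && abs(log10(ratio)) > 0.5
  if (flagged) {
    pd_warn(sprintf("self-dose check: local-absorption estimate %.3g Gy/Bq differs from reported %.3g Gy/Bq by more than half an order of magnitude",
                    d_approx, reported_d), class = "predose_self_dose")
  }
  list(d_approx_Gy_per_Bq = d_approx, ratio = ratio, flagged = flagged,
       skipped = FALSE)
}

#' @export
print.predose_dose_report <- function(x, ...) {
  cat(sprintf("<dose report: phantom '%s', nuclide %s>\n", x$phantom, x$nuclide))
  df <- data.frame(target = x$targets, d_Gy_per_Bq = signif(x$d, 6))
  if (!is.null(x$h)) df$h_Sv_per_Bq <- signif(x$h, 6)
  if (!is.null(x$d_rbe)) df[[paste0("d_rbe_", x$rbe_unit, "_per_Bq")]] <- signif(x$d_rbe, 6)
  print(df, row.names = FALSE)
  invisible(x)
}
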