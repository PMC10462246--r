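#' Run the full organ-level dosimetry pipeline
#'
#' Convenience driver chaining the protocol steps for the common ex vivo
#' design: aggregate per-region replicates to mean SUV, transpose onto the
#' phantom (blood doubling as the red-marrow surrogate when present),
#' assemble the total body by the carcass route (or accept a whole-body
#' ratio series), estimate per-region TIACs, apply the voiding-bladder model
#' and the rest-of-body closure, and compute absorbed dose coefficients.
#' Each stage is also available individually; this wrapper fixes the
#' glue choices documented below.
#'
#' Measured regions are mapped onto phantom regions via `region_map`
#' (identity for identically named regions).  Measured regions with no
#' phantom counterpart are left inside the rest of body.  A measured
#' `"Blood"` series populates the phantom red-marrow region when one exists;
#' blood itself is only used as an explicit source if the phantom flags a
#' Blood source region.  A measured `"Carcass"` series triggers the
#' carcass-route total body; otherwise supply `ratios` or a measured
#' `"Totalbody"` series.
#'
#' @param biodist Measurement table in the [read_biodist()] layout.
#' @param phantom Destination `predose_phantom`.
#' @param nuclide `predose_nuclide`.
#' @param svalues `predose_svalues` for the phantom.
#' @param animal `predose_phantom` of the assayed species, supplying the
#'   carcass/excised-region masses for the total-body assembly (the SUV is
#'   the species-invariant quantity, so the carcass sum is evaluated with
#'   the animal's masses).  Defaults to `phantom` for same-species studies.
#' @param region_map Optional mapping table ([read_region_map()]).
#' @param ratios Optional whole-body ratio `data.frame` (`time_h`,
#'   `reading`); used for the total body when no carcass/total-body series
#'   is measured.
#' @param method TIAC integration method, `"exponential"` or `"trapezoid"`.
#' @param components `Psi` for the exponential fits (`"auto"`, 1, 2 or 3).
#' @param fu,voiding_interval_h Optional voiding-bladder parameters (the
#'   bladder TIAC is derived from the total-body fit).
#' @param marrow_region Phantom red-marrow region name (skipped if absent).
#' @param use_mean_mass Passed to [aggregate_suv()].
#' @param rest_of_body Include the rest-of-body closure (requires a
#'   total-body TIAC and an S-value source for `rest_region`).
#' @param rest_region Phantom rest-of-body region name.
#' @return List with `series` (per-region `predose_tas`), `fits`,
#'   `tiacs` (list of `predose_tiac`), and `report`
#'   (`predose_dose_report`).
#' @export
run_dosimetry <- function(biodist, phantom, nuclide, svalues,
                          animal = phantom,
                          region_map = NULL, ratios = NULL,
                          method = c("exponential", "trapezoid"),
                          components = "auto",
                          fu = NULL, voiding_interval_h = NULL,
                          marrow_region = "Redmarrow",
                          use_mean_mass = FALSE,
                          rest_of_body = TRUE,
                          rest_region = "Restofbody") {
  method <- match.arg(method)
  df <- validate_biodist(biodist)
  df <- apply_region_map(df, region_map, phantom)
  measured <- unique(df$region)
  series <- lapply(measured, function(r) {
    aggregate_suv(df[df$region == r, , drop = FALSE], use_mean_mass = use_mean_mass)
  })
  names(series) <- measured

  tas <- list()
  sources <- svalues$sources
  for (r in measured) {
    pr <- unique(df$phantom_region[df$region == r])[1]
    if (is.na(pr) || !(pr %in% sources)) next
    tas[[pr]] <- transpose_region(series[[r]], phantom, nuclide, pr)
  }
  # blood surrogate for red marrow
  if ("Blood" %in% measured && marrow_region %in% phantom$regions$region &&
      marrow_region %in% sources && is.null(tas[[marrow_region]])) {
    tas[[marrow_region]] <- red_marrow_from_blood(series[["Blood"]], phantom,
                                                  nuclide, marrow_region)
  }

  # total-body series: carcass route > measured total body > ratio route
  tb_tas <- NULL
  if ("Carcass" %in% measured) {
    excised <- series[setdiff(names(series), c("Carcass", "Totalbody"))]
    tb_conc <- total_body_from_carcass(series[["Carcass"]], unname(excised), animal)
    tb_tas <- total_body_fraction(tb_conc, nuclide)
  } else if ("Totalbody" %in% measured) {
    tb_tas <- total_body_fraction(series[["Totalbody"]], nuclide)
  } else if (!is.null(ratios)) {
    tb_tas <- total_body_from_ratios(ratios)
  }

  estimate <- function(s) {
    if (method == "trapezoid") {
      list(fit = NULL, tiac = tiac_trapezoid(s, nuclide))
    } else {
      f <- fit_exponentials(s, nuclide, components = components)
      list(fit = f, tiac = tiac_from_fit(f))
    }
  }
  fits <- list()
  tiacs <- list()
  for (r in names(tas)) {
    est <- estimate(tas[[r]])
    fits[[r]] <- est$fit
    tiacs[[r]] <- est$tiac
  }

  tb_fit <- NULL
  if (!is.null(tb_tas)) {
    # total-body clearance parameters always come from exponential regression
    tb_fit <- fit_exponentials(tb_tas, nuclide, components = components)
    fits[["Totalbody"]] <- tb_fit
    tiacs[["Totalbody"]] <- tiac_from_fit(tb_fit)
  }

  if (!is.null(fu) && !is.null(voiding_interval_h)) {
    if (is.null(tb_fit)) {
      pd_stop("bladder model needs a total-body fit: supply a carcass/total-body series or whole-body ratios")
    }
    tiacs[["Bladder"]] <- tiac_bladder(tb_fit, fu, voiding_interval_h)
  }

  if (rest_of_body && !is.null(tb_fit) && rest_region %in% sources) {
    explicit <- tiacs[setdiff(names(tiacs), c("Totalbody", rest_region))]
    tiacs[[rest_region]] <- tiac_rest_of_body(tiacs[["Totalbody"]], unname(explicit))
    tiacs[[rest_region]]$region <- rest_region
  }

  dose_in <- tiacs[intersect(names(tiacs), sources)]
  report <- absorbed_dose(unname(dose_in), svalues, phantom = phantom,
                          nuclide = nuclide)
  list(series = series, tas = tas, fits = fits, tiacs = tiacs, report = report)
}
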