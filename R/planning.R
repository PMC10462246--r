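#' Plan measurement time points by the empirical spacing rule
#'
#' Generates `n` sampling times from an (anticipated) effective half-life
#' `Te` of the source region of interest:
#' \deqn{T_i = T_{min} + (T_{max} - T_{min}) \left(\frac{i-1}{n-1}\right)^{1.5}}
#' with \eqn{T_{min} = T_e/(n-1)} and
#' \eqn{T_{max} = 1.5 \, n \, T_e / (0.15 n + 1)}.  The power 1.5 front-loads
#' the schedule so fast clearance components are resolved while the last
#' point still reaches several effective half-lives.
#'
#' @param n Number of time points (>= 2).
#' @param te_h Effective half-life in hours
#'   (`Te = ln 2 / (lambda_b + lambda_p)`).
#' @return An object of class `predose_schedule` with element `times_h`.
#' @seealso [plan_icru()] for the fixed five-point multiples schedule,
#'   [effective_half_life()].
#' @export
plan_empirical <- function(n, te_h) {
  n <- pd_num1(n, "n")
  te_h <- pd_num1(te_h, "te_h")
  if (n < 2 || n != round(n)) pd_stop("n must be an integer >= 2")
  if (te_h <= 0) pd_stop("effective half-life must be > 0")
  n <- as.integer(n)
  tmin <- te_h / (n - 1)
  tmax <- 1.5 * n * te_h / (0.15 * n + 1)
  i <- seq_len(n)
  times <- tmin + (tmax - tmin) * ((i - 1) / (n - 1))^1.5
  structure(list(n = n, te_h = te_h, times_h = times, method = "empirical"),
            class = "predose_schedule")
}

#' Plan measurement time points at the ICRU effective-half-life multiples
#'
#' The fixed five-point schedule `Te/3, 2Te/3, 3Te/2, 3Te, 5Te`.
#'
#' @inheritParams plan_empirical
#' @return A `predose_schedule` with 5 times.
#' @export
plan_icru <- function(te_h) {
  te_h <- pd_num1(te_h, "te_h")
  if (te_h <= 0) pd_stop("effective half-life must be > 0")
  times <- te_h * c(1 / 3, 2 / 3, 3 / 2, 3, 5)
  structure(list(n = 5L, te_h = te_h, times_h = times, method = "icru"),
            class = "predose_schedule")
}

#' Effective half-life from biological and physical rate constants
#'
#' `Te = ln 2 / (lambda_b + lambda_p)`; equivalently
#' `1/Te = 1/Tb + 1/Tp`.
#'
#' @param lambda_b Biological clearance rate constant (1/h).
#' @param nuclide A `predose_nuclide` supplying `lambda_p`.
#' @return Effective half-life in hours.
#' @export
effective_half_life <- function(lambda_b, nuclide) {
  stopifnot(inherits(nuclide, "predose_nuclide"))
  if (any(lambda_b + nuclide$lambda_p <= 0)) {
    pd_stop("lambda_b + lambda_p must be > 0")
  }
  log(2) / (lambda_b + nuclide$lambda_p)
}

#' @export
print.predose_schedule <- function(x, ...) {
  cat(sprintf("<%s schedule: n = %d, Te = %.4g h>\n", x$method, x$n, x$te_h))
  cat(paste(signif(x$times_h, 3), collapse = ", "), "h\n")
  invisible(x)
}

#' @export
format.predose_schedule <- function(x, ...) {
  paste0("time_h\n", paste(signif(x$times_h, 3), collapse = "\n"))
}
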