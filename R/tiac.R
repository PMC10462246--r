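#' Construct a TIAC result
#'
#' The time-integrated activity coefficient (TIAC) is the number of nuclear
#' transformations occurring in a source region per unit administered
#' activity over the (infinite) dose-integration period; units of hours.
#' For any source region the TIAC cannot exceed the radionuclide mean
#' lifetime `1/lambda_p` — complete local decay of the entire administered
#' activity.
#'
#' @param region Source region name.
#' @param tiac_h TIAC in hours (>= 0).
#' @param method One of `"trapezoid"`, `"exponential"`, `"bladder"`,
#'   `"rest_of_body"`, `"physical_decay_only"`, `"simulation"`.
#' @param components Optional per-component or per-term breakdown.
#' @param se Optional standard error (h).
#' @param lambda_p Physical decay constant used (1/h); enables the
#'   `1/lambda_p` bound check.
#' @return An object of class `predose_tiac`.
#' @export
tiac_result <- function(region, tiac_h, method, components = NULL, se = NULL,
                        lambda_p = NA_real_) {
  tiac_h <- pd_num1(tiac_h, "tiac_h")
  if (tiac_h < 0) pd_stop("TIAC must be >= 0")
  if (is.finite(lambda_p) && lambda_p > 0 &&
      tiac_h > 1 / lambda_p * (1 + 1e-9)) {
    pd_warn(sprintf("TIAC %.6g h for '%s' exceeds the mean lifetime 1/lambda_p = %.6g h",
                    tiac_h, region, 1 / lambda_p),
            class = "predose_tiac_bound")
  }
  structure(list(region = as.character(region), tiac_h = tiac_h,
                 method = method, components = components, se = se,
                 lambda_p = lambda_p),
            class = "predose_tiac")
}

#' @export
print.predose_tiac <- function(x, ...) {
  cat(sprintf("<TIAC '%s': %.6g h (%s)>\n", x$region, x$tiac_h, x$method))
  invisible(x)
}

#' TIAC by trapezoidal integration
#'
#' Approximates the time-activity curve as piecewise linear between the
#' measured points and adds the standard head and tail contributions:
#' \deqn{\tilde a \approx T_1 a(T_1)
#'   + \sum_{i=1}^{n-1} \frac{a_{i+1}+a_i}{2}(T_{i+1}-T_i)
#'   + \frac{a(T_n)}{\lambda_p}}
#' The head term assumes the fraction of administered activity at injection
#' approximately equals that at the first time point; the tail term
#' conservatively assumes elimination by physical decay only after the last
#' time point.
#'
#' @param series `predose_tas` with at least two points.
#' @param nuclide `predose_nuclide` with `lambda_p > 0`.
#' @return A `predose_tiac` with a `components` breakdown
#'   (`head`, `trapezoids`, `tail`).
#' @export
tiac_trapezoid <- function(series, nuclide) {
  stopifnot(inherits(series, "predose_tas"), inherits(nuclide, "predose_nuclide"))
  t <- series$time_h
  a <- series$a
  n <- length(t)
  if (n < 2L) {
    pd_stop("trapezoidal integration needs >= 2 time points; use the exponential or physical-decay-only method for a single point")
  }
  if (is.unsorted(t, strictly = TRUE)) pd_stop("times must be strictly increasing")
  lp <- nuclide$lambda_p
  if (lp <= 0) pd_stop("lambda_p must be > 0")
  head_term <- t[1] * a[1]
  mid_term <- sum((a[-1] + a[-n]) / 2 * diff(t))
  tail_term <- a[n] / lp
  tiac_result(series$region, head_term + mid_term + tail_term,
              method = "trapezoid",
              components = c(head = head_term, trapezoids = mid_term,
                             tail = tail_term),
              lambda_p = lp)
}

#' TIAC from a multi-exponential fit (analytic integral)
#'
#' Integrating the fitted sum of exponentials over an infinite
#' dose-integration period gives the closed form
#' \deqn{\tilde a = \sum_\psi \frac{c_\psi}{\lambda_{b,\psi} + \lambda_p}.}
#'
#' @param fit A `predose_fit` from [fit_exponentials()].
#' @return A `predose_tiac` with per-component breakdown.  A delta-method
#'   standard error is attached when the fit covariance is available
#'   (non-normative; the protocol itself prescribes no uncertainty
#'   propagation for the TIAC).
#' @export
tiac_from_fit <- function(fit) {
  stopifnot(inherits(fit, "predose_fit"))
  if (!isTRUE(fit$converged)) {
    pd_stop(sprintf("fit for region '%s' did not converge; TIAC not evaluated", fit$region))
  }
  leff <- fit$lambda_b + fit$lambda_p
  comp <- fit$c / leff
  se <- NULL
  if (!is.null(fit$vcov) && all(is.finite(fit$vcov))) {
    # gradient of sum(c/(lb+lp)) wrt (c_1..c_psi, lb_1..lb_psi)
    g <- c(1 / leff, -fit$c / leff^2)
    v <- drop(t(g) %*% fit$vcov %*% g)
    if (is.finite(v) && v >= 0) se <- sqrt(v)
  }
  tiac_result(fit$region, sum(comp), method = "exponential",
              components = setNames(comp, paste0("component", seq_along(comp))),
              se = se, lambda_p = fit$lambda_p)
}

#' TIAC for a region cleared by physical decay only
#'
#' With no biological elimination (`lambda_b = 0`, zero-time amplitude `a0`)
#' the TIAC equals `a0` times the radionuclide mean lifetime `1/lambda_p`.
#'
#' @param nuclide `predose_nuclide`.
#' @param region Region name (default `"Totalbody"`).
#' @param a0 Fraction of administered activity present at time 0 (default 1).
#' @return A `predose_tiac`.
#' @export
tiac_physical_decay <- function(nuclide, region = "Totalbody", a0 = 1) {
  stopifnot(inherits(nuclide, "predose_nuclide"))
  tiac_result(region, a0 / nuclide$lambda_p, method = "physical_decay_only",
              lambda_p = nuclide$lambda_p)
}

#' Urinary-bladder TIAC from total-body clearance (voiding bladder model)
#'
#' The bladder fills from the biological-excretion flux of each total-body
#' clearance component, its content decays physically, and it empties
#' completely every `voiding_interval_h` hours.  Summing the per-cycle
#' integrals in closed form gives, per clearance component,
#' \deqn{\tilde a(Bladder) = \sum_\psi f_{u,\psi}
#'   \left[\frac{1 - e^{-\lambda_p T_V}}{\lambda_p}
#'       - \frac{1 - e^{-(\lambda_{b,\psi}+\lambda_p) T_V}}
#'              {\lambda_{b,\psi}+\lambda_p}\right]
#'   \frac{1}{1 - e^{-(\lambda_{b,\psi}+\lambda_p) T_V}}}
#' where `fu` is the fraction of administered activity ultimately excreted
#' in urine via component psi and `TV` the voiding interval.  The closed
#' form is certified against the discrete filling/voiding simulator
#' [tiac_bladder_sim()].
#'
#' @param total_body_fit `predose_fit` of the TOTAL-BODY time-activity curve.
#' @param fu Urinary fractions per clearance component (each in \[0,1\],
#'   summing to at most 1); length must match the number of fitted
#'   components.
#' @param voiding_interval_h Bladder voiding interval TV in hours (> 0).
#' @return A `predose_tiac` for region `"Bladder"`.
#' @export
tiac_bladder <- function(total_body_fit, fu, voiding_interval_h) {
  stopifnot(inherits(total_body_fit, "predose_fit"))
  tv <- pd_num1(voiding_interval_h, "voiding_interval_h")
  if (tv <= 0) pd_stop("voiding interval must be > 0")
  psi <- total_body_fit$psi
  if (length(fu) == 1L && psi > 1L) fu <- rep(fu / psi, psi)
  if (length(fu) != psi) {
    pd_stop(sprintf("fu has length %d but the total-body fit has %d component(s)",
                    length(fu), psi))
  }
  if (any(fu < 0 | fu > 1) || sum(fu) > 1 + 1e-12) {
    pd_stop("urinary fractions fu must lie in [0,1] and sum to at most 1")
  }
  lb <- total_body_fit$lambda_b
  lp <- total_body_fit$lambda_p
  if (any(fu > 0 & lb <= 0)) {
    pd_stop("fu > 0 assigned to a component with lambda_b = 0: no biological excretion to route")
  }
  comp <- vapply(seq_len(psi), function(k) {
    if (fu[k] == 0) return(0)
    le <- lb[k] + lp
    # expm1 keeps the TV -> 0 limit numerically clean
    bracket <- (-expm1(-lp * tv)) / lp - (-expm1(-le * tv)) / le
    fu[k] * bracket / (-expm1(-le * tv))
  }, 0)
  tiac_result("Bladder", sum(comp), method = "bladder",
              components = setNames(comp, paste0("component", seq_len(psi))),
              lambda_p = lp)
}

#' Discrete filling/decay/voiding bladder simulator
#'
#' Independent numerical reference for [tiac_bladder()]: the bladder content
#' obeys `B'(t) = sum_psi fu_psi lambda_b_psi exp(-(lambda_b_psi+lambda_p) t)
#' - lambda_p B(t)` and is instantaneously emptied every `voiding_interval_h`
#' hours.  The content is integrated cycle by cycle (classical Runge-Kutta
#' with the integral carried as a second state variable) until the remaining
#' cycles contribute less than `tol` of the accumulated total; after
#' `max_sim_cycles` simulated cycles the strictly geometric per-cycle decay
#' is extrapolated from the measured cycle ratio.
#'
#' @param fu Urinary fractions per clearance component.
#' @param lambda_b Biological rate constants per component (1/h).
#' @param lambda_p Physical decay constant (1/h).
#' @param voiding_interval_h Voiding interval in hours.
#' @param steps_per_cycle Runge-Kutta steps per voiding cycle.
#' @param tol Relative tail tolerance.
#' @param max_sim_cycles Cycles simulated before geometric extrapolation.
#' @return Bladder TIAC in hours (plain number).
#' @export
tiac_bladder_sim <- function(fu, lambda_b, lambda_p, voiding_interval_h,
                             steps_per_cycle = 256L, tol = 1e-10,
                             max_sim_cycles = 400L) {
  stopifnot(length(fu) == length(lambda_b))
  tv <- voiding_interval_h
  h <- tv / steps_per_cycle
  inflow <- function(s) sum(fu * lambda_b * exp(-(lambda_b + lambda_p) * s))
  total <- 0
  prev_cycle <- NA_real_
  k <- 0L
  repeat {
    t0 <- k * tv
    B <- 0          # bladder voided at cycle start
    I <- 0          # integral of content over this cycle
    for (j in seq_len(steps_per_cycle)) {
      s <- t0 + (j - 1) * h
      f1B <- inflow(s) - lambda_p * B
      f1I <- B
      B2 <- B + h / 2 * f1B
      f2B <- inflow(s + h / 2) - lambda_p * B2
      f2I <- B2
      B3 <- B + h / 2 * f2B
      f3B <- inflow(s + h / 2) - lambda_p * B3
      f3I <- B3
      B4 <- B + h * f3B
      f4B <- inflow(s + h) - lambda_p * B4
      f4I <- B4
      I <- I + h / 6 * (f1I + 2 * f2I + 2 * f3I + f4I)
      B <- B + h / 6 * (f1B + 2 * f2B + 2 * f3B + f4B)
    }
    total <- total + I
    k <- k + 1L
    if (total > 0 && I < tol * total) break
    if (k >= max_sim_cycles) {
      # inflow decays exponentially, so per-cycle integrals are geometric;
      # extrapolate the tail from the observed ratio
      r <- I / prev_cycle
      if (is.finite(r) && r < 1) total <- total + I * r / (1 - r)
      break
    }
    prev_cycle <- I
  }
  total
}

#' Rest-of-body TIAC by subtraction
#'
#' The rest of body is the composite source region holding all activity not
#' explicitly assigned to a sampled region:
#' `a~(RoB) = a~(Totalbody) - sum a~(rS*)` over the explicitly derived
#' source regions.
#'
#' @param total `predose_tiac` for the total body.
#' @param explicit_sources List of `predose_tiac` for the explicitly assigned
#'   (disjoint) source regions.
#' @param clamp If the difference is negative: `FALSE` (default) raises an
#'   error with a per-source breakdown; `TRUE` clamps to zero with a warning.
#' @return A `predose_tiac` for region `"Restofbody"`.
#' @export
tiac_rest_of_body <- function(total, explicit_sources = list(), clamp = FALSE) {
  stopifnot(inherits(total, "predose_tiac"))
  if (inherits(explicit_sources, "predose_tiac")) explicit_sources <- list(explicit_sources)
  regs <- vapply(explicit_sources, function(x) x$region, "")
  if (anyDuplicated(regs)) {
    pd_stop(sprintf("explicit source(s) listed more than once: %s",
                    paste(unique(regs[duplicated(regs)]), collapse = ", ")))
  }
  vals <- vapply(explicit_sources, function(x) x$tiac_h, 0)
  rob <- total$tiac_h - sum(vals)
  if (rob < 0) {
    breakdown <- paste(sprintf("%s = %.6g h", regs, vals), collapse = "; ")
    if (!clamp) {
      pd_stop(sprintf("explicit-source TIACs (%s; sum %.6g h) exceed the total-body TIAC (%.6g h)",
                      breakdown, sum(vals), total$tiac_h))
    }
    pd_warn(sprintf("rest-of-body TIAC negative (%.6g h); clamped to 0. Sources: %s",
                    rob, breakdown), class = "predose_rob_clamped")
    rob <- 0
  }
  tiac_result("Restofbody", rob, method = "rest_of_body",
              components = setNames(vals, regs), lambda_p = total$lambda_p)
}
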