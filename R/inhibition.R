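# Inhibition analysis: percent inhibition with error propagation, Hill
# dose-response IC50 fitting, incubation time-course fitting, and
# reversibility/recovery quantification.

#' Percent inhibition of a treated permeability relative to control
#'
#' `inhibition = 100 (1 - P_treated / P_control)`, with SEM propagated to
#' first order from the two estimates.
#'
#' @param p_treated,p_control [permeability_estimate()]s of the same kind and
#'   temperature; `p_control > 0`.
#' @return list with `inhibition_pct` and `sem`.
#' @export
#' @examples
#' percent_inhibition(permeability_estimate(0.11 * 1.8e-5, "glycerol"),
#'                    permeability_estimate(1.8e-5, "glycerol"))
percent_inhibition <- function(p_treated, p_control) {
  stopifnot(inherits(p_treated, "permeability_estimate"),
            inherits(p_control, "permeability_estimate"))
  if (p_treated$kind != p_control$kind)
    aqp_stop("permeability kinds differ between treated and control")
  if (!is.na(p_treated$temperature_c) && !is.na(p_control$temperature_c) &&
      p_treated$temperature_c != p_control$temperature_c)
    aqp_stop("temperatures differ between treated and control")
  if (p_control$value <= 0)
    aqp_stop("control permeability must be > 0")
  vt <- p_treated$value; vc <- p_control$value
  sem <- 100 * sqrt((p_treated$sem / vc)^2 +
                      (vt * p_control$sem / vc^2)^2)
  list(inhibition_pct = 100 * (1 - vt / vc), sem = sem)
}

#' Fit a log-logistic (Hill) dose-response curve
#'
#' Nonlinear least-squares fit of
#' \deqn{y = y_{min} + (y_{max} - y_{min}) / (1 + 10^{((\log_{10} IC_{50} - x) H)}),}
#' where `y` is percent inhibition and `x = log10(concentration in uM)`
#' (the standard log-logistic convention: the concentration enters the
#' printed Hill equation on the log10 scale, which keeps the exponent
#' dimensionless). Zero-concentration points are excluded from the fit (log
#' undefined) but, when present, checked against `ymin`. Reported errors are
#' asymptotic standard errors of the least-squares fit.
#'
#' @param concentrations_um inhibitor concentrations in uM.
#' @param inhibition_pct percent inhibition at each concentration.
#' @param weights optional fit weights (e.g. `1/sem^2`); unweighted by
#'   default.
#' @param ymin lower asymptote; fixed at 0 by default (no inhibition at zero
#'   dose). Set to `NULL` to fit it.
#' @param ymax upper asymptote; fitted by default, or a fixed number.
#' @return an object of class `dose_response_fit` with `ic50_um`,
#'   `ic50_se`, `log_ic50`, `log_ic50_se`, `hill`, `hill_se`, `ymin`, `ymax`,
#'   `ymax_se`, `rss`, `n_points`.
#' @export
fit_dose_response <- function(concentrations_um, inhibition_pct,
                              weights = NULL, ymin = 0, ymax = NULL) {
  if (length(concentrations_um) != length(inhibition_pct))
    aqp_stop("'concentrations_um' and 'inhibition_pct' lengths differ")
  pos <- concentrations_um > 0
  if (any(!pos)) {
    y0 <- inhibition_pct[!pos]
    if (!is.null(ymin) && any(abs(y0 - ymin) > 25))
      warning("zero-dose inhibition far from ymin; check the control",
              call. = FALSE)
  }
  x <- log10(concentrations_um[pos])
  y <- inhibition_pct[pos]
  w <- if (is.null(weights)) rep(1, length(y)) else weights[pos]
  if (length(unique(concentrations_um[pos])) < 4L)
    aqp_stop("need at least 4 distinct positive concentrations")
  if (diff(range(y)) < 1e-8 * max(1, abs(mean(y))))
    aqp_stop("no transition in the data: dose-response unidentifiable",
             class = "aquaflow_fit_error")

  fit_ymin <- is.null(ymin)
  fit_ymax <- is.null(ymax)
  ymin0 <- if (fit_ymin) min(y) else ymin
  ymax0 <- if (fit_ymax) max(y) else ymax
  l10_0 <- x[which.min(abs(y - (ymin0 + ymax0) / 2))]

  start <- c(l10 = unname(l10_0), h = 1)
  lower <- c(l10 = -Inf, h = 1e-6)
  if (fit_ymax) { start <- c(start, ymax_ = unname(ymax0))
                  lower <- c(lower, ymax_ = -Inf) }
  if (fit_ymin) { start <- c(start, ymin_ = unname(ymin0))
                  lower <- c(lower, ymin_ = -Inf) }
  sw <- sqrt(w)
  model_y <- function(p) {
    lo <- if (fit_ymin) p[["ymin_"]] else ymin
    hi <- if (fit_ymax) p[["ymax_"]] else ymax
    lo + (hi - lo) / (1 + 10^((p[["l10"]] - x) * p[["h"]]))
  }
  fit <- nls_lm_fit(function(p) sw * (model_y(p) - y), start, lower)
  if (is.null(fit))
    aqp_stop("dose-response fit failed to converge",
             class = "aquaflow_fit_error")
  cf <- fit$par; se <- fit$se
  l10 <- unname(cf[["l10"]])
  l10_se <- unname(se[["l10"]])
  structure(list(ic50_um = 10^l10,
                 ic50_se = log(10) * 10^l10 * l10_se,
                 log_ic50 = l10, log_ic50_se = l10_se,
                 hill = unname(cf[["h"]]), hill_se = unname(se[["h"]]),
                 ymin = if (fit_ymin) unname(cf[["ymin_"]]) else ymin,
                 ymax = if (fit_ymax) unname(cf[["ymax_"]]) else ymax,
                 ymax_se = if (fit_ymax) unname(se[["ymax_"]]) else 0,
                 rss = fit$rss, n_points = length(y)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> IC50 = %.4g +/- %.2g uM, Hill = %.3g +/- %.2g, ymax = %.3g%%, n = %d\n",
              x$ic50_um, x$ic50_se, x$hill, x$hill_se, x$ymax, x$n_points))
  invisible(x)
}

#' Fit the incubation-time dependence of inhibition
#'
#' Fits `inhibition(t) = baseline + plateau (1 - exp(-t / tau))` -- the
#' exponential approach of inhibition to its maximum during pre-incubation
#' (equivalently, an exponential decay of activity toward the inhibited
#' plateau). `baseline` is fixed at 0 by default (no inhibition before
#' exposure).
#'
#' @param incubation_times_min incubation times in min.
#' @param inhibition_pct percent inhibition at each time.
#' @param baseline fixed baseline inhibition; `NULL` to fit it.
#' @return an object of class `time_course_fit` with `tau_min`, `tau_se`,
#'   `plateau_pct`, `plateau_se`, `baseline_pct`, `rss`, `n_points`.
#' @export
fit_time_dependence <- function(incubation_times_min, inhibition_pct,
                                baseline = 0) {
  t <- incubation_times_min; y <- inhibition_pct
  if (length(t) != length(y)) aqp_stop("input lengths differ")
  if (length(unique(t)) < 4L)
    aqp_stop("need at least 4 distinct incubation times")
  if (coef(lm(y ~ t))[2] <= 0)
    warning("inhibition does not increase with incubation time", call. = FALSE)
  fit_base <- is.null(baseline)
  base0 <- if (fit_base) min(y) else baseline
  plateau0 <- max(y) - base0
  # start tau at the time of ~63% of the plateau
  tau0 <- t[which.min(abs((y - base0) - 0.632 * plateau0))]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t[t > 0]) / 3

  start <- c(plateau = unname(plateau0), tau = unname(tau0))
  lower <- c(plateau = 0, tau = 1e-9)
  if (fit_base) { start <- c(start, base_ = unname(base0))
                  lower <- c(lower, base_ = -Inf) }
  model_y <- function(p) {
    base <- if (fit_base) p[["base_"]] else base0
    base + p[["plateau"]] * (1 - exp(-t / p[["tau"]]))
  }
  fit <- nls_lm_fit(function(p) model_y(p) - y, start, lower)
  if (is.null(fit))
    aqp_stop("time-course fit failed to converge",
             class = "aquaflow_fit_error")
  cf <- fit$par; se <- fit$se
  structure(list(tau_min = unname(cf[["tau"]]), tau_se = unname(se[["tau"]]),
                 plateau_pct = unname(cf[["plateau"]]),
                 plateau_se = unname(se[["plateau"]]),
                 baseline_pct = if (fit_base) unname(cf[["base_"]]) else base0,
                 rss = fit$rss, n_points = length(y)),
            class = "time_course_fit")
}

#' @export
print.time_course_fit <- function(x, ...) {
  cat(sprintf("<time_course_fit> tau = %.4g min, plateau = %.4g%%, n = %d\n",
              x$tau_min, x$plateau_pct, x$n_points))
  invisible(x)
}

#' Recovery of permeability after washout/competition treatment
#'
#' `recovery = 100 (P_recovered - P_inhibited) / (P_control - P_inhibited)`:
#' 0% means no recovery from the inhibited level, 100% full return to
#' control. Values outside `[0, 100 + tolerance]` (possible with noisy
#' estimates) are clipped with a warning.
#'
#' @param p_control,p_inhibited,p_recovered [permeability_estimate()]s or
#'   bare numbers; requires `p_control > p_inhibited >= 0`.
#' @param tolerance allowed overshoot above 100%, in percentage points.
#' @return percent recovery.
#' @export
#' @examples
#' recovery_fraction(1.0, 0.1, 0.91) # 90
recovery_fraction <- function(p_control, p_inhibited, p_recovered,
                              tolerance = 5) {
  val <- function(x) if (inherits(x, "permeability_estimate")) x$value else x
  pc <- val(p_control); pi_ <- val(p_inhibited); pr <- val(p_recovered)
  if (pi_ < 0) aqp_stop("inhibited permeability must be >= 0")
  if (pc <= pi_)
    aqp_stop("recovery undefined: control does not exceed inhibited permeability")
  raw <- 100 * (pr - pi_) / (pc - pi_)
  if (raw < 0) {
    warning(sprintf("recovery %.3g%% below 0; clipped", raw), call. = FALSE)
    return(0)
  }
  if (raw > 100 + tolerance) {
    warning(sprintf("recovery %.3g%% above 100%%; clipped", raw), call. = FALSE)
    return(100 + tolerance)
  }
  raw
}
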