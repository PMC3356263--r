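# Kinetic parameter extraction from scattering traces: single and double
# exponential relaxation fits, the amplitude-weighted biexponential rate,
# biphasic phase splitting, and the reswelling linear slope.

# Extract (t, I) inside a window; window = c(start, end) in s or NULL = all.
window_points <- function(trace, window) {
  stopifnot(inherits(trace, "scatter_trace"))
  if (is.null(window)) window <- range(trace$times)
  if (length(window) != 2L || window[2] <= window[1])
    aqp_stop("'window' must be c(start, end) with end > start")
  sel <- trace$times >= window[1] & trace$times <= window[2]
  list(t = trace$times[sel], i = trace$intensities[sel],
       window = as.numeric(window))
}

# Default fit window: from the first sample to the time at which the smoothed
# signal has completed 90% of its total excursion (the trace end if the
# relaxation has not plateaued). Truncating the late phase keeps the
# single-exponential rate close to its initial-volume linearization on
# shrinkage kinetics, whose local rate grows as the cell approaches
# equilibrium (see the methods vignette).
default_fit_window <- function(trace, q = 0.90) {
  s <- moving_average(trace$intensities,
                      max(5L, ceiling(0.01 * length(trace$intensities))))
  total <- s[length(s)] - s[1]
  if (abs(total) == 0) return(range(trace$times))
  frac <- (s - s[1]) / total
  idx <- which(frac >= q)
  end <- if (length(idx)) trace$times[min(idx)] else max(trace$times)
  c(trace$times[1], max(end, trace$times[min(length(trace$times), 5L)]))
}

#' Fit a single-exponential relaxation to a scattering trace
#'
#' Least-squares fit of `I(t) = plateau + (I0 - plateau) exp(-k (t - t_start))`
#' over the window; the sign of the relaxation (rising shrinkage signal or
#' decaying reswelling signal) is detected automatically from the trend.
#' Initialization is deterministic: plateau from the tail mean, initial value
#' from the first samples, `k` from a log-linear regression on the first
#' third of the relaxation.
#'
#' @param trace a [scatter_trace()].
#' @param window fit window `c(start, end)` in s; default from the first
#'   sample to the time of 90% of the total amplitude (truncating the late
#'   phase keeps the rate constant close to its initial-volume
#'   linearization on osmotic shrinkage kinetics).
#' @return an object of class `rate_fit` with fields `k` (s^-1), `k_se`,
#'   `amplitude` (signed total signal change, a.u.), `offset` (fitted
#'   plateau), `rss`, `n_points` and `window`.
#' @export
fit_single_exponential <- function(trace, window = NULL) {
  if (is.null(window)) window <- default_fit_window(trace)
  pts <- window_points(trace, window)
  if (length(pts$t) < 5L)
    aqp_stop("fit window must contain at least 5 samples")
  t0 <- pts$t[1]
  tt <- pts$t - t0
  ii <- pts$i
  noise <- estimate_noise(ii)
  n_tail <- max(3L, ceiling(0.1 * length(ii)))
  plateau0 <- mean(tail(ii, n_tail))
  i00 <- mean(head(ii, min(5L, length(ii))))
  amp0 <- plateau0 - i00
  if (abs(amp0) < max(3 * noise, .Machine$double.eps * max(1, abs(plateau0))))
    aqp_stop("no relaxation: amplitude indistinguishable from zero",
             class = "aquaflow_no_relaxation_error")

  # log-linear start for k on the first third of the relaxation
  third <- tt <= tt[length(tt)] / 3
  resid0 <- abs(ii - plateau0)
  use <- third & resid0 > max(noise, 1e-12 * abs(amp0))
  k0 <- if (sum(use) >= 3) {
    sl <- coef(lm(log(resid0[use]) ~ tt[use]))[2]
    if (is.finite(sl) && sl < 0) -sl else 1 / max(tt[length(tt)] / 3, 1e-9)
  } else 1 / max(tt[length(tt)] / 3, 1e-9)

  resid_fn <- function(p)
    p[["plateau"]] + (p[["i0"]] - p[["plateau"]]) * exp(-p[["k"]] * tt) - ii
  fit <- nls_lm_fit(resid_fn,
                    start = c(plateau = unname(plateau0), i0 = unname(i00),
                              k = unname(as.numeric(k0))),
                    lower = c(plateau = -Inf, i0 = -Inf, k = 1e-12))
  if (is.null(fit))
    aqp_stop("single-exponential fit failed to converge",
             class = "aquaflow_fit_error")
  cf <- fit$par
  structure(list(k = unname(cf[["k"]]), k_se = unname(fit$se[["k"]]),
                 amplitude = unname(cf[["plateau"]] - cf[["i0"]]),
                 offset = unname(cf[["plateau"]]),
                 rss = fit$rss, n_points = length(tt),
                 window = pts$window, noise = noise, model = "exponential"),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit %s> k = %.6g s^-1 (se %.2g), amplitude = %.4g, n = %d, rss = %.3g\n",
              x$model, x$k, x$k_se, x$amplitude, x$n_points, x$rss))
  invisible(x)
}

#' Fit a double-exponential relaxation
#'
#' Fits `I(t) = plateau - dI1 exp(-k1 t') - dI2 exp(-k2 t')` (`t' = t -
#' t_start`; `dI` signed so the same form covers rising and decaying traces)
#' and orders the components so `k1 <= k2` (slow, fast). Model selection
#' against the single-exponential fit uses an F-ratio test: if the rss
#' improvement is not significant at `f_alpha`, or if the two rates agree
#' within 1% (an unidentifiable degenerate fit), the single-exponential
#' result is returned in collapsed form (`k1 = k2 = k`, `dI2 = 0`).
#'
#' @param trace a [scatter_trace()].
#' @param window fit window, as in [fit_single_exponential()].
#' @param f_alpha significance threshold of the F-ratio acceptance test.
#' @return an object of class `biexp_fit` with fields `k1 <= k2`, `dI1`,
#'   `dI2`, `offset`, `rss`, `n_points`, `collapsed`.
#' @seealso [weighted_rate()]
#' @export
fit_double_exponential <- function(trace, window = NULL, f_alpha = 0.01) {
  single <- fit_single_exponential(trace, window) # also screens the trace
  if (is.null(window)) window <- default_fit_window(trace)
  pts <- window_points(trace, window)
  tt <- pts$t - pts$t[1]
  ii <- pts$i
  amp <- single$amplitude
  collapsed <- function() {
    structure(list(k1 = single$k, k2 = single$k,
                   dI1 = single$amplitude, dI2 = 0,
                   offset = single$offset, rss = single$rss,
                   n_points = single$n_points, window = single$window,
                   collapsed = TRUE),
              class = "biexp_fit")
  }
  resid_fn <- function(p)
    p[["plateau"]] - p[["d1"]] * exp(-p[["k1"]] * tt) -
      p[["d2"]] * exp(-p[["k2"]] * tt) - ii
  fit <- nls_lm_fit(resid_fn,
                    start = c(plateau = single$offset, d1 = amp / 2,
                              d2 = amp / 2, k1 = single$k / 2,
                              k2 = single$k * 2),
                    lower = c(plateau = -Inf, d1 = -Inf, d2 = -Inf,
                              k1 = 1e-12, k2 = 1e-12))
  if (is.null(fit)) return(collapsed())
  cf <- fit$par
  ks <- c(cf[["k1"]], cf[["k2"]]); ds <- c(cf[["d1"]], cf[["d2"]])
  ord <- order(ks)
  ks <- ks[ord]; ds <- ds[ord]
  rss2 <- fit$rss
  n <- length(tt)
  # F-ratio for the 2 extra parameters of the biexponential model
  fstat <- ((single$rss - rss2) / 2) / (rss2 / max(n - 4, 1))
  pval <- if (is.finite(fstat) && fstat > 0)
    stats::pf(fstat, 2, max(n - 4, 1), lower.tail = FALSE) else 1
  if (pval > f_alpha) return(collapsed())
  if (abs(ks[2] - ks[1]) / ks[2] < 0.01) return(collapsed())
  structure(list(k1 = ks[1], k2 = ks[2], dI1 = ds[1], dI2 = ds[2],
                 offset = unname(cf[["plateau"]]), rss = rss2,
                 n_points = n, window = pts$window, collapsed = FALSE),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit%s> k1 = %.6g, k2 = %.6g s^-1; dI1 = %.4g, dI2 = %.4g; k_de = %.6g s^-1\n",
              if (x$collapsed) " (collapsed to single)" else "",
              x$k1, x$k2, x$dI1, x$dI2, weighted_rate(x)))
  invisible(x)
}

#' Amplitude-weighted average rate constant of a biexponential fit
#'
#' `k_de = (dI1 k1 + dI2 k2) / (dI1 + dI2)`, the weighted rate used in place
#' of a single-exponential constant for cells whose shrinkage is
#' biexponential. Invariant under swapping the component labels.
#'
#' @param fit a `biexp_fit`, or a list/vector with `k1`, `k2`, `dI1`, `dI2`.
#' @return `k_de` in s^-1.
#' @export
#' @examples
#' weighted_rate(list(k1 = 2, k2 = 4, dI1 = 1, dI2 = 3)) # 3.5
weighted_rate <- function(fit) {
  f <- as.list(fit)
  tot <- f$dI1 + f$dI2
  if (!is_number(tot) || tot == 0)
    aqp_stop("undefined weighted rate: dI1 + dI2 = 0",
             class = "aquaflow_fit_error")
  (f$dI1 * f$k1 + f$dI2 * f$k2) / tot
}

#' Split a biphasic trace into shrinkage and reswelling windows
#'
#' Locates the global intensity extremum of the smoothed trace (moving
#' average of width `max(5 samples, 1% of the trace length)`), refines it on
#' a lightly smoothed (5-sample) version within one smoothing width, and
#' returns the two phase windows. The reswelling window excludes a guard band
#' of `guard` samples after the extremum. A trace without a significant
#' second phase raises a "not biphasic" error.
#'
#' @param trace a [scatter_trace()].
#' @param guard number of samples excluded after the extremum.
#' @return list with elements `shrink` and `reswell` (each `c(start, end)` in
#'   s) and `t_extremum`, the refined extremum time.
#' @export
split_phases <- function(trace, guard = 3L) {
  stopifnot(inherits(trace, "scatter_trace"))
  n <- length(trace$times)
  w <- max(5L, ceiling(0.01 * n))
  s <- moving_average(trace$intensities, w)
  noise <- estimate_noise(trace$intensities)
  floor_amp <- max(3 * noise, 1e-9 * max(abs(s)))
  margin <- max(3L, as.integer(guard))

  # A biphasic trace has one interior extremum with a significant excursion
  # on both sides (a peak when shrinkage raises intensity, the usual optics;
  # a trough if the mapping is inverted). Evaluate both candidates on the
  # smoothed trace and keep the earliest valid one: the first (shrinkage)
  # phase is the fast one.
  refine <- function(i0, maximum) {
    if (noise < 1e-10 * max(abs(s - s[1]))) { # effectively noise-free
      hits <- if (maximum) which.max(trace$intensities)
              else which.min(trace$intensities)
      return(hits)
    }
    lo <- max(1L, i0 - w); hi <- min(n, i0 + w)
    sm <- moving_average(trace$intensities[lo:hi],
                         max(5L, ceiling(w / 3)))
    lo - 1L + if (maximum) which.max(sm) else which.min(sm)
  }
  valid <- function(i_star) {
    i_star > margin && i_star < n - margin &&
      abs(s[i_star] - s[1]) >= floor_amp &&
      abs(s[n] - s[i_star]) >= floor_amp
  }
  cand <- c(peak = refine(which.max(s), TRUE),
            trough = refine(which.min(s), FALSE))
  cand <- cand[vapply(cand, valid, TRUE)]
  if (!length(cand))
    aqp_stop("trace is not biphasic: no interior extremum with a significant second phase",
             class = "aquaflow_not_biphasic_error")
  i_star <- min(cand)
  # model-based refinement: both phases are near-exponential, so the
  # extremum of a biexponential fit (with starts taken from the two phases)
  # locates the true turning point far better than any symmetric smoother,
  # whose window biases the argmax toward the slow phase.
  if (noise >= 1e-10 * max(abs(s - s[1]))) {
    t_ref <- biexp_extremum(trace, i_star, w, noise)
    if (is.finite(t_ref) && t_ref > trace$times[margin] &&
        t_ref < trace$times[n - margin]) {
      i_ref <- which.min(abs(trace$times - t_ref))
      if (valid(i_ref)) i_star <- i_ref
    }
  }
  list(shrink = c(trace$times[1], trace$times[i_star]),
       reswell = c(trace$times[min(n, i_star + guard)], trace$times[n]),
       t_extremum = trace$times[i_star])
}

# Analytic extremum of a biexponential fit to a biphasic trace, used by
# split_phases. Starts: slow rate from a log-linear fit of the post-extremum
# decay, fast rate from the pre-extremum 63% rise time, amplitudes from the
# endpoints. Returns NA when the fit fails or has no interior extremum.
biexp_extremum <- function(trace, i0, w, noise) {
  n <- length(trace$times)
  tt <- trace$times - trace$times[1]
  ii <- trace$intensities
  s <- moving_average(ii, w)
  plateau0 <- mean(tail(ii, max(3L, ceiling(0.05 * n))))
  sign_peak <- if (s[i0] >= s[1]) 1 else -1   # peak vs trough
  post <- seq(min(n, i0 + w), n)
  dec <- sign_peak * (ii[post] - plateau0)
  usable <- dec > max(10 * noise, 1e-12)
  if (sum(usable) < 10L) return(NA_real_)
  cf <- tryCatch(coef(lm(log(dec[usable]) ~ tt[post][usable])),
                 error = function(e) NULL)
  if (is.null(cf) || !is.finite(cf[2]) || cf[2] >= 0) return(NA_real_)
  ks0 <- unname(-cf[2])
  d1_0 <- unname(-sign_peak * exp(cf[1]))
  rise <- sign_peak * (s[seq_len(i0)] - s[1])
  i63 <- which(rise >= 0.63 * rise[i0])[1]
  if (!is.finite(i63) || tt[i63] <= 0) return(NA_real_)
  kf0 <- 1 / tt[i63]
  d2_0 <- unname(-(ii[1] - plateau0 + d1_0))
  resid_fn <- function(p)
    p[["p"]] - p[["d1"]] * exp(-p[["k1"]] * tt) -
      p[["d2"]] * exp(-p[["k2"]] * tt) - ii
  fit <- nls_lm_fit(resid_fn,
                    start = c(p = unname(plateau0), d1 = d1_0, d2 = d2_0,
                              k1 = ks0, k2 = kf0),
                    lower = c(-Inf, -Inf, -Inf, 1e-9, 1e-9), maxiter = 300)
  if (is.null(fit)) return(NA_real_)
  cc <- fit$par
  ratio <- -(cc[["d2"]] * cc[["k2"]]) / (cc[["d1"]] * cc[["k1"]])
  if (!is.finite(ratio) || ratio <= 0 || cc[["k2"]] == cc[["k1"]])
    return(NA_real_)
  trace$times[1] + log(ratio) / (cc[["k2"]] - cc[["k1"]])
}

#' Linear reswelling slope of a trace window
#'
#' Ordinary least-squares slope of intensity against time over a window of
#' the reswelling phase (the PC12 protocol expresses glycerol entry as this
#' slope). The normalized slope divides by the total signal amplitude of the
#' trace, giving s^-1 units.
#'
#' @param trace a [scatter_trace()].
#' @param window `c(start, end)` in s; by default the first quarter of the
#'   reswelling phase found by [split_phases()].
#' @return list with `slope` (a.u. s^-1), `slope_se`, `normalized_slope`
#'   (s^-1), `n_points`, `window`.
#' @export
fit_reswelling_slope <- function(trace, window = NULL) {
  if (is.null(window)) {
    ph <- split_phases(trace)
    window <- c(ph$reswell[1],
                ph$reswell[1] + 0.25 * diff(ph$reswell))
  }
  pts <- window_points(trace, window)
  if (length(pts$t) < 5L)
    aqp_stop("slope window must contain at least 5 points")
  fit <- lm(pts$i ~ pts$t)
  slope <- unname(coef(fit)[2])
  # slope SE computed directly (summary.lm warns on perfect fits)
  rss <- sum(fit$residuals^2)
  sxx <- sum((pts$t - mean(pts$t))^2)
  amp <- diff(range(moving_average(trace$intensities,
                                   max(5L, ceiling(0.01 * length(trace$intensities))))))
  list(slope = slope,
       slope_se = sqrt(rss / (length(pts$t) - 2) / sxx),
       normalized_slope = if (amp > 0) slope / amp else NA_real_,
       n_points = length(pts$t), window = pts$window)
}
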