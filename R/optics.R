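# Optical rendering: volume traces -> 90-degree scattered-light intensity
# records with instrument dead time, finite sampling rate and additive
# Gaussian noise.

#' A stopped-flow scattered-light intensity record
#'
#' @param times sampling times in s, strictly increasing, starting at or
#'   after the instrument dead time.
#' @param intensities intensities in a.u., all finite.
#' @param temperature_c sample temperature in degC.
#' @param condition named list of condition metadata (compound,
#'   concentration_um, incubation_min, solute, replicate, ...).
#' @param seed RNG seed used to generate the noise (NA for real data).
#' @param meta optional extra metadata list.
#' @return an object of class `scatter_trace`.
#' @export
scatter_trace <- function(times, intensities, temperature_c = NA_real_,
                          condition = list(), seed = NA_integer_,
                          meta = list()) {
  if (length(times) != length(intensities) || length(times) < 2L)
    aqp_stop("'times' and 'intensities' must have equal length >= 2")
  if (any(diff(times) <= 0))
    aqp_stop("'times' must be strictly increasing")
  if (!all(is.finite(intensities)))
    aqp_stop("'intensities' must all be finite")
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 temperature_c = temperature_c,
                 condition = condition, seed = seed, meta = meta),
            class = "scatter_trace")
}

#' @export
print.scatter_trace <- function(x, ...) {
  cond <- x$condition
  desc <- if (length(cond)) paste(names(cond), unlist(lapply(cond, format)),
                                  sep = "=", collapse = ", ") else "none"
  cat(sprintf("<scatter_trace> %d points, t = [%g, %g] s, I = [%.4g, %.4g] a.u.\n  condition: %s\n",
              length(x$times), min(x$times), max(x$times),
              min(x$intensities), max(x$intensities), desc))
  invisible(x)
}

#' @export
as.data.frame.scatter_trace <- function(x, ...) {
  data.frame(time_s = x$times, intensity = x$intensities)
}

#' Render a volume trace into a scattered-light intensity trace
#'
#' Applies the affine optical model `I(t) = alpha + beta (1 - V(t)/V0) +
#' noise` (intensity rises as cells shrink), resamples at the acquisition
#' rate, and drops samples before the instrument dead time. Because the
#' mapping is affine in volume, exponential rate constants of the volume
#' kinetics are preserved exactly.
#'
#' @param trace a [volume_trace()].
#' @param optics an [optics_spec()].
#' @param seed RNG seed for the noise realization (NULL for unseeded noise;
#'   ignored when `noise_sigma = 0`).
#' @param condition condition metadata to attach.
#' @return a [scatter_trace()].
#' @export
volume_to_intensity <- function(trace, optics = optics_spec(), seed = NULL,
                                condition = list()) {
  stopifnot(inherits(optics, "optics_spec"))
  if (!inherits(trace, "volume_trace") || length(trace$times) < 2L)
    aqp_stop("'trace' must be a volume_trace with at least 2 points")
  t_end <- max(trace$times)
  if (t_end <= optics$dead_time)
    aqp_stop("trace ends before the instrument dead time")
  grid <- seq(optics$dead_time, t_end, by = 1 / optics$sampling_rate)
  v <- approx(trace$times, trace$volumes_fl, grid, rule = 2)$y
  ideal <- optics$alpha + optics$beta * (1 - v / trace$v0_fl)
  noise <- if (optics$noise_sigma > 0) {
    with_seed(seed, rnorm(length(grid), sd = optics$noise_sigma))
  } else rep(0, length(grid))
  scatter_trace(grid, ideal + noise,
                temperature_c = trace$temperature_c,
                condition = condition,
                seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                meta = list(dead_time = optics$dead_time,
                            sampling_rate = optics$sampling_rate))
}

#' Generate replicate noisy traces of one experimental condition
#'
#' Renders `n` scattering traces of the same volume kinetics that differ only
#' in their noise realization. Replicate `r` uses the derived seed
#' `derive_seed(seed, r)`, so a fixed `seed` reproduces the replicate set
#' bitwise.
#'
#' @param trace a [volume_trace()] for the condition.
#' @param optics an [optics_spec()].
#' @param n number of replicates (>= 1); stopped-flow work typically
#'   analyses 5--7.
#' @param seed base seed for the condition.
#' @param condition condition metadata; each replicate gets a `replicate`
#'   field appended.
#' @return list of `n` [scatter_trace()] objects.
#' @export
make_replicates <- function(trace, optics = optics_spec(), n = 5L,
                            seed = 1L, condition = list()) {
  if (!is_number(n) || n < 1) aqp_stop("'n' must be >= 1")
  lapply(seq_len(n), function(r) {
    volume_to_intensity(trace, optics, seed = derive_seed(seed, r),
                        condition = modifyList(condition,
                                               list(replicate = r)))
  })
}
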