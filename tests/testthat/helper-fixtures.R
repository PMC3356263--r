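# Shared fixtures and independent oracles for the test suite.

# Cells used throughout. The b = 0 variant has a fully osmotically active
# volume, the assumption under which the classic rate->Pf estimator is exact.
rbc0 <- function() hrbc_cell(inactive_fraction = 0)
rbc <- function() hrbc_cell()

const18 <- function() physical_constants(vw_molar = 18.0)

# An exact single-exponential scattering trace (rising form).
exp_trace <- function(k = 3, amp = 0.2, offset = 1, t_end = 3, dt = 0.001,
                      sigma = 0, seed = NULL) {
  t <- seq(0.002, t_end, by = dt)
  i <- offset + amp * (1 - exp(-k * (t - t[1])))
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    i <- i + rnorm(length(i), sd = sigma)
  }
  scatter_trace(t, i)
}

# Brute-force oracle for the single-exponential rate: profile the two linear
# parameters (offset, amplitude) at each k on a grid and return the k with
# the smallest rss. Independent of the nls-based fitting path.
grid_search_k <- function(trace, k_grid) {
  tt <- trace$times - trace$times[1]
  ii <- trace$intensities
  rss <- vapply(k_grid, function(k) {
    basis <- 1 - exp(-k * tt)
    f <- lm.fit(cbind(1, basis), ii)
    sum(f$residuals^2)
  }, 0)
  k_grid[which.min(rss)]
}

# Brute-force oracle for the log-logistic dose-response fit (ymin = 0):
# profile ymax linearly on a (log10 IC50, Hill) grid.
grid_search_dose <- function(conc_um, y, l10_grid, h_grid) {
  x <- log10(conc_um)
  best <- c(rss = Inf, l10 = NA, h = NA)
  for (h in h_grid) {
    for (l10 in l10_grid) {
      basis <- 1 / (1 + 10^((l10 - x) * h))
      ymax <- sum(basis * y) / sum(basis^2)
      rss <- sum((y - ymax * basis)^2)
      if (rss < best["rss"]) best <- c(rss = rss, l10 = l10, h = h)
    }
  }
  best
}

# A glycerol-gradient biphasic simulation shared by several tests.
glycerol_sim <- function(cell = rbc(), pf = 4.2e-2, psolute = 1.8e-5,
                         t_end = 120, dt = 0.01) {
  simulate_volume(cell, bath_spec(300, "glycerol", 100), pf = pf,
                  psolute = psolute, times = seq(0, t_end, by = dt),
                  temperature_c = 23)
}

# Count direction changes of a volume series, ignoring steps below eps
# (integrator-tolerance wiggle at equilibrium is not an extremum).
count_turning_points <- function(v, eps = 1e-6 * max(abs(v))) {
  dv <- diff(v)
  dv <- dv[abs(dv) > eps]
  sum(diff(sign(dv)) != 0)
}
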