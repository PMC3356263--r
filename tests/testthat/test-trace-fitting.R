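# Trace fitting: exponential fits, the weighted biexponential rate, phase
# splitting and the reswelling slope.

test_that("single-exponential fit recovers exact model data to high precision", {
  st <- exp_trace(k = 3, amp = 0.2, offset = 1)
  fit <- fit_single_exponential(st, window = range(st$times))
  expect_lt(abs(fit$k - 3) / 3, 1e-6)
  expect_equal(fit$amplitude, 0.2, tolerance = 1e-6)
  expect_equal(fit$offset, 1.2, tolerance = 1e-6)
  # decaying mirror is detected automatically
  std <- scatter_trace(st$times, 1.2 - 0.2 * (1 - exp(-3 * (st$times - 0.002))))
  fitd <- fit_single_exponential(std, window = range(std$times))
  expect_lt(abs(fitd$k - 3) / 3, 1e-6)
  expect_lt(fitd$amplitude, 0)
})

test_that("noisy single-exponential fit matches the brute-force grid oracle", {
  st <- exp_trace(k = 3, sigma = 0.005, seed = 1)
  fit <- fit_single_exponential(st, window = range(st$times))
  expect_lt(abs(fit$k - 3) / 3, 0.05)
  k_grid <- grid_search_k(st, seq(2, 4, by = 0.005))
  expect_lt(abs(fit$k - k_grid), 0.005 + 1e-9)
})

test_that("constant and sub-noise traces raise a no-relaxation error", {
  t <- seq(0.002, 1, by = 0.001)
  expect_error(fit_single_exponential(scatter_trace(t, rep(1, length(t)))),
               class = "aquaflow_no_relaxation_error")
  set.seed(5)
  expect_error(
    fit_single_exponential(scatter_trace(t, 1 + rnorm(length(t), sd = 0.01))),
    class = "aquaflow_no_relaxation_error")
})

test_that("rate estimates are invariant under affine intensity transforms", {
  # monotone relaxation, default window
  sim <- exp_trace(k = 3)
  f1 <- fit_single_exponential(sim)
  f2 <- fit_single_exponential(scatter_trace(sim$times,
                                             7.3 * sim$intensities - 2.1))
  expect_lt(abs(f2$k - f1$k) / f1$k, 1e-9)
  # reswelling phase of a noiseless biphasic trace, explicit window
  sg <- volume_to_intensity(glycerol_sim(), solute_optics(noise_sigma = 0))
  win <- split_phases(sg)$reswell
  g1 <- fit_single_exponential(sg, window = win)
  g2 <- fit_single_exponential(scatter_trace(sg$times,
                                             7.3 * sg$intensities - 2.1),
                               window = win)
  expect_lt(abs(g2$k - g1$k) / g1$k, 1e-9)
})

test_that("weighted biexponential rate follows its defining formula", {
  expect_equal(weighted_rate(list(k1 = 2, k2 = 4, dI1 = 1, dI2 = 3)), 3.5)
  expect_equal(weighted_rate(list(k1 = 1.7, k2 = 9, dI1 = 1, dI2 = 0)), 1.7)
  # equal amplitudes: plain mean; label swap leaves it unchanged
  expect_equal(weighted_rate(list(k1 = 2, k2 = 5, dI1 = 2, dI2 = 2)), 3.5)
  expect_equal(weighted_rate(list(k1 = 5, k2 = 2, dI1 = 2, dI2 = 2)), 3.5)
  expect_error(weighted_rate(list(k1 = 1, k2 = 2, dI1 = 1, dI2 = -1)),
               class = "aquaflow_fit_error")
})

test_that("double-exponential fit separates two rates and orders them", {
  t <- seq(0.002, 3, by = 0.001)
  i <- 0.1 + 0.08 * (1 - exp(-1.2 * (t - 0.002))) +
    0.04 * (1 - exp(-6 * (t - 0.002)))
  set.seed(2)
  st <- scatter_trace(t, i + rnorm(length(t), sd = 1e-4))
  fit <- fit_double_exponential(st, window = range(st$times))
  expect_false(fit$collapsed)
  expect_lte(fit$k1, fit$k2)
  expect_lt(abs(fit$k1 - 1.2) / 1.2, 0.05)
  expect_lt(abs(fit$k2 - 6) / 6, 0.05)
  kde_true <- (0.08 * 1.2 + 0.04 * 6) / 0.12
  expect_lt(abs(weighted_rate(fit) - kde_true) / kde_true, 0.05)
})

test_that("double-exponential fit collapses on a genuine single exponential", {
  st <- exp_trace(k = 3, sigma = 0.002, seed = 4)
  fit <- fit_double_exponential(st, window = range(st$times))
  expect_true(fit$collapsed)
  expect_equal(fit$k1, fit$k2)
  expect_equal(weighted_rate(fit),
               fit_single_exponential(st, window = range(st$times))$k)
})

test_that("split_phases finds the volume minimum of biphasic traces", {
  tr <- glycerol_sim()
  t_true <- tr$times[which.min(tr$volumes_fl)]
  # noise-free: exactly the discrete argmax of the intensity trace
  st0 <- volume_to_intensity(tr, solute_optics(noise_sigma = 0))
  ph0 <- split_phases(st0)
  expect_equal(ph0$t_extremum, st0$times[which.max(st0$intensities)])
  expect_lt(abs(ph0$t_extremum - t_true) / t_true, 0.05)
  # default noise, several seeds: within 5% of the simulator's truth
  errs <- vapply(1:8, function(s) {
    st <- volume_to_intensity(tr, solute_optics(), seed = s)
    abs(split_phases(st)$t_extremum - t_true) / t_true
  }, 0)
  expect_lt(median(errs), 0.05)
  # windows are ordered with a guard band
  expect_lt(ph0$shrink[2], ph0$reswell[1])
  expect_gte(ph0$reswell[1] - ph0$shrink[2], 2 * 0.01) # >= guard samples
})

test_that("monotone traces are rejected as not biphasic", {
  cell <- rbc()
  tr <- simulate_volume(cell, bath_spec(400), pf = 4.2e-2,
                        times = seq(0, 3, by = 0.001))
  st <- volume_to_intensity(tr, water_optics(), seed = 2)
  expect_error(split_phases(st), class = "aquaflow_not_biphasic_error")
})

test_that("reswelling slope matches lines exactly and the simulator derivative closely", {
  # exact line: slope recovered exactly, constant trace: slope 0
  t <- seq(0.002, 10, by = 0.01)
  st <- scatter_trace(t, 2 - 0.1 * t)
  sl <- fit_reswelling_slope(st, window = c(1, 5))
  expect_equal(sl$slope, -0.1, tolerance = 1e-12)
  stc <- scatter_trace(t, rep(1.5, length(t)))
  expect_equal(fit_reswelling_slope(stc, window = c(1, 5))$slope, 0,
               tolerance = 1e-12)
  expect_error(fit_reswelling_slope(st, window = c(1, 1.02)),
               class = "aquaflow_input_error")
  # early reswell slope vs the instantaneous derivative at the window midpoint
  tr <- glycerol_sim()
  st0 <- volume_to_intensity(tr, solute_optics(noise_sigma = 0))
  ph <- split_phases(st0)
  win <- c(ph$t_extremum + 0.5, ph$t_extremum + 2.5)
  sl2 <- fit_reswelling_slope(st0, win)
  tm <- mean(win); h <- 0.005
  dv <- (approx(tr$times, tr$volumes_fl, tm + h)$y -
           approx(tr$times, tr$volumes_fl, tm - h)$y) / (2 * h)
  didt <- -1 / 82 * dv   # beta = 1, d(1 - V/V0)/dt
  expect_lt(abs(sl2$slope - didt) / abs(didt), 0.02)
})

test_that("fitted rate on small-gradient shrinkage has low noise-driven error", {
  # Monte-Carlo over seeds at the default noise level
  st_base <- exp_trace(k = 3, amp = 0.125, offset = 0.1, t_end = 2)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    st <- scatter_trace(st_base$times,
                        st_base$intensities +
                          rnorm(length(st_base$times), sd = 0.002))
    abs(fit_single_exponential(st)$k - 3) / 3
  }, 0)
  expect_lt(median(errs), 0.03)
})
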