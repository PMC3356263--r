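# Synthetic data: optical rendering, replicate generation and the
# experiment-bundle generators.

test_that("optical mapping is affine in relative volume change", {
  t <- seq(0, 1, by = 0.01)
  # constant V = V0 -> constant I = alpha
  tr <- volume_trace(t, rep(82, length(t)), v0_fl = 82)
  st <- volume_to_intensity(tr, optics_spec(alpha = 1, beta = 0.5,
                                            noise_sigma = 0,
                                            sampling_rate = 100))
  expect_true(all(abs(st$intensities - 1) < 1e-12))
  # V/V0 = 0.8, alpha = 1, beta = 0.5 -> I = 1.1
  tr2 <- volume_trace(t, rep(0.8 * 82, length(t)), v0_fl = 82)
  st2 <- volume_to_intensity(tr2, optics_spec(alpha = 1, beta = 0.5,
                                              noise_sigma = 0,
                                              sampling_rate = 100))
  expect_true(all(abs(st2$intensities - 1.1) < 1e-12))
})

test_that("rendering preserves exponential rate constants and drops the dead time", {
  k <- 2.5
  t <- seq(0, 4, by = 0.001)
  v <- 70 + 12 * exp(-k * t)   # exponential volume relaxation
  tr <- volume_trace(t, v, v0_fl = 82)
  st <- volume_to_intensity(tr, optics_spec(noise_sigma = 0,
                                            sampling_rate = 1000))
  expect_gte(st$times[1], 0.002)
  fit <- fit_single_exponential(st, window = range(st$times))
  expect_lt(abs(fit$k - k) / k, 1e-6)
})

test_that("replicates are deterministic in the seed and differ only by noise", {
  t <- seq(0, 2, by = 0.002)
  tr <- volume_trace(t, 70 + 12 * exp(-3 * t), v0_fl = 82)
  # noiseless replicates identical
  reps0 <- make_replicates(tr, optics_spec(noise_sigma = 0,
                                           sampling_rate = 500), n = 5,
                           seed = 1)
  expect_true(all(vapply(reps0[-1], function(r)
    identical(r$intensities, reps0[[1]]$intensities), TRUE)))
  # fixed seed reproduces bitwise; different replicates differ
  o <- optics_spec(sampling_rate = 500)
  a <- make_replicates(tr, o, n = 3, seed = 42)
  b <- make_replicates(tr, o, n = 3, seed = 42)
  expect_identical(lapply(a, `[[`, "intensities"),
                   lapply(b, `[[`, "intensities"))
  expect_false(identical(a[[1]]$intensities, a[[2]]$intensities))
  # replicate scatter of fitted rates shrinks with the noise level
  sd_k <- function(sigma) {
    reps <- make_replicates(tr, optics_spec(noise_sigma = sigma,
                                            sampling_rate = 500),
                            n = 7, seed = 3)
    sd(vapply(reps, function(r)
      fit_single_exponential(r, window = range(r$times))$k, 0))
  }
  expect_lt(sd_k(2e-4), sd_k(2e-3) / 3)
})

test_that("derived seeds are deterministic, in range, and distinct across indices", {
  expect_identical(derive_seed(1, 2, 3), derive_seed(1, 2, 3))
  seeds <- outer(1:20, 1:7, function(i, r)
    mapply(function(a, b) derive_seed(123, a, b), i, r))
  expect_true(all(seeds >= 0 & seeds < 2^31 - 1))
  expect_equal(anyDuplicated(c(seeds)), 0)
})

test_that("dose-response generator applies the Hill law with correct limits", {
  truth <- inhibition_truth(p_control = 1.8e-5, ic50_um = 1, hill = 1,
                            max_inhibition = 1)
  # c -> 0: no inhibition; c = ic50 with full max inhibition: half permeability
  expect_equal(hill_inhibition(0, truth), 0)
  expect_equal(hill_inhibition(1, truth), 0.5)
  expect_equal(hill_inhibition(1e9, truth), 1, tolerance = 1e-6)
  b <- make_dose_response_experiment(truth, concentrations_um = c(0.5, 1, 2),
                                     n_reps = 2, seed = 1, duration_s = 30)
  expect_equal(length(b$manifest$conditions), 4) # control added
  expect_equal(b$manifest$conditions[[1]]$concentration_um, 0)
  expect_equal(b$manifest$truth$ic50_um, 1)
})

test_that("time-course generator anchors t = 0 at the control permeability", {
  truth <- inhibition_truth(tau_incubation_min = 10, max_inhibition = 0.9)
  b <- make_time_course_experiment(truth,
                                   incubation_times_min = c(0, 10, 30, 60),
                                   n_reps = 1, seed = 2, duration_s = 30)
  expect_equal(b$manifest$conditions[[1]]$role, "control")
  # plateau: at t >> tau inhibition approaches max_inhibition
  expect_equal(truth$max_inhibition * (1 - exp(-60 / 10)), 0.8978,
               tolerance = 1e-3)
})

test_that("Arrhenius generator follows the Arrhenius law", {
  # ea = 0: permeability identical at all temperatures
  expect_equal(arrhenius_permeability(0, 1e-5, 23, c(10, 25, 37)),
               rep(1e-5, 3))
  # closed-form two-point check: doubling between 283 K and 310 K
  ea2 <- log(2) * 1.987e-3 / (1 / 283 - 1 / 310)
  p310 <- arrhenius_permeability(ea2, 1e-5, 283 - 273.15, 310 - 273.15)
  expect_equal(p310, 2e-5, tolerance = 1e-9)
  expect_error(make_arrhenius_experiment(temperatures_c = c(10, 20)),
               class = "aquaflow_input_error")
})

test_that("generated bundles are pure functions of their seed", {
  args <- list(concentrations_um = c(0.5, 2), n_reps = 2, seed = 99,
               duration_s = 20)
  b1 <- do.call(make_dose_response_experiment, args)
  b2 <- do.call(make_dose_response_experiment, args)
  expect_identical(b1$traces, b2$traces)
  expect_identical(b1$manifest, b2$manifest)
})

test_that("mean fitted permeability over replicates is nearly unbiased at default noise", {
  cell <- rbc0()
  bath <- bath_spec(310)  # small gradient: linear regime
  tr <- simulate_volume(cell, bath, pf = 4.2e-2,
                        times = seq(0, 3, by = 0.001))
  reps <- make_replicates(tr, water_optics(), n = 50, seed = 7)
  pfs <- vapply(reps, function(r)
    pf_from_rate(fit_single_exponential(r)$k, cell,
                 bath_osm_inf_mosm(bath))$value, 0)
  expect_lt(abs(mean(pfs) - 4.2e-2) / 4.2e-2, 0.02)
})
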