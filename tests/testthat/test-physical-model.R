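# Forward osmotic model: Boyle-van't Hoff equilibria, volume kinetics and the
# linearized rate constant.

test_that("equilibrium volume follows the Boyle-van't Hoff relation", {
  cell <- cell_spec(82, 91.1, inactive_fraction = 0.5, iso_mosm = 300)
  # isotonic identity
  expect_equal(equilibrium_volume(cell, bath_spec(300)), 82)
  # closed-form arithmetic: 41 + 41 * 300/400
  expect_equal(equilibrium_volume(cell, bath_spec(400)), 71.75)
  # infinitely hypertonic limit -> osmotically inactive volume b*V0
  expect_equal(equilibrium_volume(cell, bath_spec(1e12)), 41, tolerance = 1e-9)
  # permeant species is osmotically silent at equilibrium
  expect_equal(equilibrium_volume(cell, bath_spec(300, "glycerol", 100)), 82)
  expect_error(equilibrium_volume(cell, bath_spec(0)),
               class = "aquaflow_bath_error")
})

test_that("isotonic bath is a fixed point of the volume dynamics", {
  tr <- simulate_volume(rbc(), bath_spec(300), pf = 4.2e-2,
                        times = seq(0, 5, by = 0.01))
  expect_lt(max(abs(tr$volumes_fl - 82)) / 82, 1e-9)
})

test_that("impermeant-gradient shrinkage is monotone and reaches the closed-form equilibrium", {
  cell <- rbc()
  bath <- bath_spec(400)
  tr <- simulate_volume(cell, bath, pf = 4.2e-2, times = seq(0, 10, by = 0.01))
  expect_true(all(diff(tr$volumes_fl) <= 1e-12))
  expect_lt(abs(tail(tr$volumes_fl, 1) - equilibrium_volume(cell, bath)) /
              equilibrium_volume(cell, bath), 0.001)
  # volumes never cross the osmotically inactive floor
  expect_true(all(tr$volumes_fl > cell$inactive_fraction * cell$v0_fl))
})

test_that("permeant-solute traces are biphasic and return to the initial volume", {
  tr <- glycerol_sim()
  v <- tr$volumes_fl
  expect_lt(min(v), 82)                      # shrinks below V0
  expect_gt(tail(v, 1), min(v))              # reswells
  expect_lt(abs(tail(v, 1) - 82) / 82, 0.005)
  # exactly one interior minimum
  expect_equal(count_turning_points(v), 1)
})

test_that("larger Pf shrinks faster on the same gradient", {
  cell <- rbc()
  bath <- bath_spec(400)
  t_half <- function(pf) {
    tr <- simulate_volume(cell, bath, pf = pf, times = seq(0, 20, by = 0.002))
    v_half <- (82 + equilibrium_volume(cell, bath)) / 2
    tr$times[which(tr$volumes_fl <= v_half)[1]]
  }
  halves <- vapply(c(0.01, 0.02, 0.042, 0.08), t_half, 0)
  expect_true(all(diff(halves) < 0))
})

test_that("linearized rate matches the direct arithmetic oracle and inverts pf_from_rate", {
  # pf = 4.2e-2 cm/s, V0/A = 9e-5 cm, osm = 4e-4 mol/cm^3 -> k = 3.36 1/s
  k <- linearized_rate(rbc0(), bath_spec(400), 4.2e-2, const18())
  expect_equal(k, 4.2e-2 / 9e-5 * 18 * 4e-4, tolerance = 1e-12)
  expect_equal(k, 3.36, tolerance = 1e-12)
  expect_equal(linearized_rate(rbc0(), bath_spec(400), 0), 0)
  # round trip through the estimator is exact
  pf_back <- pf_from_rate(k, rbc0(), 4e-4, const18())$value
  expect_equal(pf_back, 4.2e-2, tolerance = 1e-12)
  expect_error(linearized_rate(rbc0(), bath_spec(300, "glycerol", 100), 0.01),
               class = "aquaflow_input_error")
})

test_that("single-exponential fit of simulated shrinkage agrees with the linearized rate", {
  cell <- rbc0()
  for (case in list(list(grad = 10, tol = 0.02), list(grad = 100, tol = 0.10))) {
    bath <- bath_spec(300 + case$grad)
    tr <- simulate_volume(cell, bath, pf = 4.2e-2,
                          times = seq(0, 3, by = 0.001))
    fit <- fit_single_exponential(
      volume_to_intensity(tr, water_optics(noise_sigma = 0)))
    expect_lt(abs(fit$k - linearized_rate(cell, bath, 4.2e-2)) /
                linearized_rate(cell, bath, 4.2e-2), case$tol)
  }
})

test_that("simulation input validation", {
  expect_error(simulate_volume(rbc(), bath_spec(400), pf = 4.2e-2,
                               times = c(0, 1, 1)),
               class = "aquaflow_input_error")
  expect_error(simulate_volume(rbc(), bath_spec(400), pf = 0,
                               times = c(0, 1, 2)),
               class = "aquaflow_input_error")
})

test_that("cell geometry helpers", {
  expect_equal(v0_over_a(rbc0()), 9e-5, tolerance = 1e-12)
  pc12 <- pc12_cell()
  r <- (3 * 1076 / (4 * pi))^(1 / 3)
  expect_equal(pc12$area_um2, 4 * pi * r^2)
  expect_equal(pc12$inactive_fraction, 0.30)
  expect_error(cell_spec(82, 91, inactive_fraction = 1),
               class = "aquaflow_input_error")
  expect_error(physical_constants(vw_molar = 20),
               class = "aquaflow_input_error")
})
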