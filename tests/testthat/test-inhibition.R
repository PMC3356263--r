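# Inhibition analysis: percent inhibition, Hill IC50 fitting, incubation
# time course and recovery.

pe <- function(v, sem = 0, kind = "glycerol")
  permeability_estimate(v, kind, sem = sem)

test_that("percent inhibition and its error propagation", {
  expect_equal(percent_inhibition(pe(0.11 * 1.8e-5), pe(1.8e-5))$inhibition_pct,
               89, tolerance = 1e-9)
  expect_equal(percent_inhibition(pe(1.8e-5), pe(1.8e-5))$inhibition_pct, 0)
  expect_equal(percent_inhibition(pe(0), pe(1.8e-5))$inhibition_pct, 100)
  # invariance under common rescaling of both inputs
  expect_equal(percent_inhibition(pe(3e-6), pe(2e-5))$inhibition_pct,
               percent_inhibition(pe(3e-2, kind = "water"),
                                  pe(2e-1, kind = "water"))$inhibition_pct)
  # first-order propagation: exact for sem on the treated arm only
  res <- percent_inhibition(pe(1e-5, sem = 1e-6), pe(2e-5))
  expect_equal(res$sem, 100 * 1e-6 / 2e-5)
  expect_error(percent_inhibition(pe(1e-5), pe(1e-2, kind = "water")),
               class = "aquaflow_input_error")
})

test_that("dose-response fit recovers exact Hill data and matches the grid oracle", {
  conc <- c(0.1, 0.3, 1, 3, 10)
  y <- 100 / (1 + 10^((log10(1) - log10(conc)) * 1))
  fit <- fit_dose_response(conc, y)
  expect_lt(abs(fit$ic50_um - 1) / 1, 1e-6)
  expect_lt(abs(fit$hill - 1), 1e-6)
  expect_equal(fit$ymax, 100, tolerance = 1e-4)
  # logistic midpoint: y(IC50) = (ymin + ymax)/2
  mid <- fit$ymin + (fit$ymax - fit$ymin) /
    (1 + 10^((fit$log_ic50 - log10(fit$ic50_um)) * fit$hill))
  expect_equal(mid, (fit$ymin + fit$ymax) / 2)
  # brute-force grid oracle agrees within its resolution
  g <- grid_search_dose(conc, y, seq(-0.5, 0.5, by = 0.001),
                        seq(0.5, 2, by = 0.01))
  expect_lt(abs(fit$log_ic50 - g[["l10"]]), 0.001 + 1e-9)
  expect_lt(abs(fit$hill - g[["h"]]), 0.01 + 1e-9)
})

test_that("dose-response fit is invariant to concentration unit rescaling", {
  conc <- c(0.1, 0.3, 1, 3, 10)
  y <- 90 / (1 + 10^((log10(0.8) - log10(conc)) * 1.2))
  fit_um <- fit_dose_response(conc, y)
  fit_nm <- fit_dose_response(conc * 1e3, y)
  expect_equal(fit_nm$ic50_um / fit_um$ic50_um, 1e3, tolerance = 1e-6)
  expect_equal(fit_nm$hill, fit_um$hill, tolerance = 1e-6)
})

test_that("dose-response fit rejects flat or too-small designs", {
  expect_error(fit_dose_response(c(0.1, 1, 10), c(10, 50, 90)),
               class = "aquaflow_input_error")
  expect_error(fit_dose_response(c(0.1, 0.3, 1, 3, 10), rep(50, 5)),
               class = "aquaflow_fit_error")
  # zero-concentration points are excluded but validated against ymin
  y <- 100 / (1 + 10^((log10(1) - log10(c(0.1, 0.3, 1, 3, 10))) * 1))
  fit <- fit_dose_response(c(0, 0.1, 0.3, 1, 3, 10), c(0, y))
  expect_lt(abs(fit$ic50_um - 1), 1e-5)
  expect_warning(fit_dose_response(c(0, 0.1, 0.3, 1, 3, 10), c(60, y)),
                 "zero-dose")
})

test_that("incubation time-course fit recovers tau and plateau", {
  t <- c(0, 2, 5, 10, 15, 20, 30, 45)
  y <- 90 * (1 - exp(-t / 10))
  fit <- fit_time_dependence(t, y)
  expect_equal(fit$tau_min, 10, tolerance = 1e-6)
  expect_equal(fit$plateau_pct, 90, tolerance = 1e-6)
  expect_equal(fit$baseline_pct, 0)
  # model anchor: no inhibition at t = 0
  expect_equal(fit$plateau_pct * (1 - exp(-0 / fit$tau_min)), 0)
  expect_warning(fit_time_dependence(t, rev(y)), "does not increase")
  expect_error(fit_time_dependence(c(0, 10, 30), c(0, 50, 80)),
               class = "aquaflow_input_error")
})

test_that("noisy time-course recovery is accurate over many seeds", {
  t <- c(0, 2, 5, 10, 15, 20, 30, 45)
  y0 <- 90 * (1 - exp(-t / 10))
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    fit <- fit_time_dependence(t, y0 + rnorm(length(t), sd = 2))
    abs(fit$tau_min - 10) / 10
  }, 0)
  expect_lt(median(errs), 0.15)
})

test_that("recovery fraction quantifies washout reversibility", {
  expect_equal(recovery_fraction(1.0, 0.1, 0.91), 90, tolerance = 1e-9)
  expect_equal(recovery_fraction(1.0, 0.1, 1.0), 100)
  expect_equal(recovery_fraction(1.0, 0.1, 0.1), 0)
  expect_warning(r <- recovery_fraction(1.0, 0.1, 0.05), "clipped")
  expect_equal(r, 0)
  expect_warning(r2 <- recovery_fraction(1.0, 0.1, 2), "clipped")
  expect_equal(r2, 105)
  expect_error(recovery_fraction(1.0, 1.0, 0.5),
               class = "aquaflow_input_error")
})
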