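proportional_series <- function(rf = 1e16, conc = 12.2e-9 * 2^(0:7),
                                reps = 3) {
  calibration_series("p1", conc,
                     lapply(conc, function(cc) rep(rf * cc, reps)))
}

test_that("a perfectly proportional series keeps every level", {
  s <- proportional_series()
  expect_identical(detect_linear_range(s), 1:8)
})

test_that("a hard saturation plateau is pruned down to the linear levels", {
  # noiseless synthetic series saturating above level 5 of 8
  cfg <- synth_config(n_chemicals = 5, n_descriptors = 12,
                      n_informative = 2, sigma_instrument = 0,
                      sigma_area = 0, saturation_quantile = 0.625, seed = 5)
  ds <- generate_dataset(cfg)
  for (s in ds$calibration) {
    expect_identical(detect_linear_range(s), 1:5)
  }
  # idempotence: re-running on the retained levels changes nothing
  s <- ds$calibration[[3]]
  lin <- detect_linear_range(s)
  s2 <- calibration_series(s$chemical_id, s$concentrations[lin],
                           s$areas[lin])
  expect_identical(detect_linear_range(s2), seq_along(lin))
})

test_that("three-level series: all linear kept, one saturated level flags it", {
  conc <- c(1e-8, 2e-8, 4e-8)
  lin3 <- calibration_series("a", conc, list(10, 20, 40))
  expect_identical(detect_linear_range(lin3), 1:3)
  sat3 <- calibration_series("b", conc, list(10, 20, 20))
  expect_identical(detect_linear_range(sat3), integer(0))
  e <- estimate_response_factor(sat3)
  expect_false(e$ok)
  expect_identical(e$flag, "no_linear_range")
})

test_that("irreproducible replicate levels are excluded up front", {
  conc <- 12.2e-9 * 2^(0:5)
  areas <- lapply(conc, function(cc) rep(1e16 * cc, 3))
  areas[[4]] <- 1e16 * conc[4] * c(0.2, 1.0, 2.5)  # RSD >> 0.3
  s <- calibration_series("r1", conc, areas)
  expect_identical(detect_linear_range(s), c(1:3, 5:6))
})

test_that("noiseless response factors are recovered to machine precision", {
  s <- proportional_series(rf = 1e16)
  e <- estimate_response_factor(s)
  expect_true(e$ok)
  expect_equal(e$rf, 1e16, tolerance = 1e-12)
  expect_equal(e$n_linear, 8L)
  expect_identical(e$isotope_correction_factor, 1)
  # with an isotope correction the corrected slope still matches truth
  cfg <- synth_config(n_chemicals = 3, n_descriptors = 10,
                      n_informative = 2, sigma_instrument = 0,
                      sigma_area = 0, saturation_quantile = 1, seed = 4)
  ds <- generate_dataset(cfg)
  for (i in seq_len(3)) {
    e <- estimate_response_factor(ds$calibration[[i]],
                                  ds$chemicals$formula[i])
    expect_equal(e$rf, 10^ds$truth$log_rf[i], tolerance = 1e-9)
    expect_gte(e$isotope_correction_factor, 1)
  }
})

test_that("response factor estimation is scale-equivariant", {
  s <- proportional_series(rf = 2.5e15)
  e <- estimate_response_factor(s)
  s_area <- calibration_series("p1", s$concentrations,
                               lapply(s$areas, `*`, 2))
  expect_equal(estimate_response_factor(s_area)$rf, 2 * e$rf,
               tolerance = 1e-12)
  k <- 3.7
  s_conc <- calibration_series("p1", s$concentrations * k, s$areas)
  expect_equal(estimate_response_factor(s_conc)$rf, e$rf / k,
               tolerance = 1e-12)
})

test_that("a decreasing series is flagged for a non-positive slope", {
  conc <- c(1e-8, 2e-8, 4e-8, 8e-8)
  s <- calibration_series("n1", conc, list(45, 40, 30, 10))  # exact, slope < 0
  e <- estimate_response_factor(s, rel_residual_tol = 1)
  expect_false(e$ok)
  expect_identical(e$flag, "nonpositive_slope")
})

test_that("noisy slope recovery matches the analytic sampling-variance oracle", {
  # multiplicative 10% area noise, triplicates, 8 geometric levels:
  # Var(slope)/RF^2 = sigma^2 * sum((c-cbar)^2 c^2) / (sum((c-cbar)^2))^2
  cfg <- synth_config(n_chemicals = 200, sigma_area = 0.1,
                      saturation_quantile = 1, seed = 21)
  ds <- generate_dataset(cfg)
  fm <- stats::setNames(as.list(ds$chemicals$formula),
                        ds$chemicals$chemical_id)
  x <- rep(cfg$conc_levels, each = cfg$n_replicates)
  xc <- x - mean(x)
  rel_se <- cfg$sigma_area * sqrt(sum(xc^2 * x^2)) / sum(xc^2)
  p10 <- stats::pnorm(0.1 / rel_se) - stats::pnorm(-0.1 / rel_se)
  # full-range fit (no residual pruning): fraction within 10% of truth
  # agrees with the analytic law within 3 binomial SEs
  rft_full <- estimate_response_factors(ds$calibration, fm,
                                        rel_residual_tol = 1)
  rel_err_full <- abs(rft_full$rf_M_inv - 10^ds$truth$log_rf) /
    10^ds$truth$log_rf
  expect_lt(abs(mean(rel_err_full < 0.1) - p10),
            3 * sqrt(p10 * (1 - p10) / 200))
  # the default pipeline (with linear-range pruning) stays close behind
  rft <- estimate_response_factors(ds$calibration, fm)
  rel_err <- abs(rft$rf_M_inv - 10^ds$truth$log_rf) / 10^ds$truth$log_rf
  expect_true(all(rft$ok))
  expect_gte(mean(rel_err < 0.10), 0.80)
  expect_gte(mean(rel_err < 0.15), 0.90)
})
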