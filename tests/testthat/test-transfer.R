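test_that("the transfer line recovers a noiseless relationship exactly", {
  x <- seq(0, 4, length.out = 100)
  tl <- fit_transfer(x, 1.2 * x + 14.5)
  expect_lt(abs(tl$slope - 1.2), 1e-8)
  expect_lt(abs(tl$intercept - 14.5), 1e-8)
  expect_true(tl$converged)
  expect_true(all(tl$robust_weights >= 0 & tl$robust_weights <= 1))
  # two points: the interpolating line, whatever the weights
  tl2 <- fit_transfer(c(1, 3), c(15, 17.4))
  expect_equal(tl2$slope, 1.2, tolerance = 1e-10)
  expect_equal(tl2$intercept, 13.8, tolerance = 1e-10)
  expect_error(fit_transfer(rep(2, 5), rnorm(5)), "degenerate")
  expect_error(fit_transfer(1, 2), "at least 2")
})

test_that("Huber weighting resists gross outliers where OLS fails", {
  set.seed(10)
  x <- runif(100, 0, 4)
  y <- 14.5 + 1.2 * x
  out <- order(x, decreasing = TRUE)[1:10]
  y[out] <- y[out] - 3   # grossly overpredicted IE at the top of the range
  tl <- fit_transfer(x, y)
  ols <- stats::lm(y ~ x)
  expect_lt(abs(tl$slope - 1.2) / 1.2, 0.05)
  expect_gt(abs(stats::coef(ols)[2] - 1.2) / 1.2, 0.05)
  expect_lt(max(tl$robust_weights[out]), 0.2)
  # cross-check against the canonical robust-regression implementation
  if (requireNamespace("MASS", quietly = TRUE)) {
    rl <- MASS::rlm(y ~ x, maxit = 50)
    expect_equal(tl$slope, unname(stats::coef(rl)[2]), tolerance = 1e-3)
  }
})

test_that("forcing unit weights reproduces ordinary least squares", {
  set.seed(11)
  x <- rnorm(30)
  y <- 2 + 0.8 * x + rnorm(30, 0, 0.5)
  tl <- fit_transfer(x, y, k_huber = 1e12)
  ols <- stats::lm(y ~ x)
  expect_equal(tl$slope, unname(stats::coef(ols)[2]), tolerance = 1e-10)
  expect_equal(tl$intercept, unname(stats::coef(ols)[1]), tolerance = 1e-10)
  expect_true(all(tl$robust_weights == 1))
})

test_that("predicted RFs follow the fitted line", {
  tl <- structure(list(slope = 1, intercept = 0, robust_weights = 1,
                       n_points = 2, converged = TRUE),
                  class = "transfer_line")
  expect_equal(rf_from_ie(0, tl), 1)
  tl2 <- fit_transfer(c(0, 1, 2), c(14, 15.5, 17))
  # the anchor chemical at log IE = 0 maps to 10^intercept
  expect_equal(rf_from_ie(0, tl2), 10^tl2$intercept)
  ies <- seq(-1, 4, 0.5)
  expect_true(all(diff(rf_from_ie(ies, tl2)) > 0))
})

test_that("concentration prediction inverts the calibration model", {
  expect_equal(predict_concentration(1e16 * 1e-7, 1e16), 1e-7)
  expect_equal(predict_concentration(200, 1e10),
               2 * predict_concentration(100, 1e10))
  expect_error(predict_concentration(100, -1), "rf")
  # end-to-end identity: a noiseless chemical quantified with its own RF
  cfg <- synth_config(n_chemicals = 4, n_descriptors = 10,
                      n_informative = 2, sigma_instrument = 0,
                      sigma_area = 0, saturation_quantile = 0.625, seed = 6)
  ds <- generate_dataset(cfg)
  for (i in seq_len(4)) {
    s <- ds$calibration[[i]]
    frac <- monoisotopic_fraction(ds$chemicals$formula[i])
    lin <- seq_len(ds$truth$top_linear_level[i])
    pred <- predict_concentration(
      correct_area(vapply(s$areas[lin], mean, 0), frac),
      10^ds$truth$log_rf[i])
    expect_equal(pred, s$concentrations[lin], tolerance = 1e-9)
  }
})

test_that("error factor is the symmetric fold error", {
  expect_equal(error_factor(1e-7, 1e-7), 1)
  expect_equal(error_factor(10, 1), 10)
  expect_equal(error_factor(0.1, 1), 10)
  set.seed(12)
  a <- 10^runif(50, -9, -5); b <- 10^runif(50, -9, -5)
  expect_equal(error_factor(a, b), error_factor(b, a))
  expect_true(all(error_factor(a, b) >= 1))
  expect_equal(log10(error_factor(a, b)), abs(log10(a) - log10(b)),
               tolerance = 1e-12)
  expect_error(error_factor(-1, 1), "> 0")
})

test_that("error summaries aggregate per chemical", {
  r1 <- data.frame(chemical_id = c("a", "b", "c"),
                   error_factor = c(1, 2, 100))
  s1 <- summarize_errors(r1)
  expect_equal(s1$median_ef, 2)
  expect_equal(s1$mean_ef, 103 / 3, tolerance = 1e-6)
  expect_equal(s1$frac_under_10, 2 / 3)
  r2 <- data.frame(chemical_id = rep("a", 4), error_factor = rep(1, 4))
  s2 <- summarize_errors(r2)
  expect_equal(unlist(s2[c("median_ef", "mean_ef", "frac_under_10")]),
               c(median_ef = 1, mean_ef = 1, frac_under_10 = 1))
  # one bad level disqualifies the chemical from the under-10x count
  r3 <- data.frame(chemical_id = c("a", "a", "a"),
                   error_factor = c(1.1, 1.2, 12))
  expect_equal(summarize_errors(r3)$frac_under_10, 0)
})

test_that("median error factor shrinks monotonically with instrument noise", {
  set.seed(13)
  base <- rnorm(4000)
  med_ef <- vapply(c(0.4, 0.3, 0.2, 0.1, 0.05, 0),
                   function(s) stats::median(10^abs(s * base)), 0)
  expect_true(all(diff(med_ef) <= 0))
  expect_equal(med_ef[6], 1)
})
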