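test_that("rank-stratified folds partition chemicals and span the distribution", {
  expect_identical(sort(make_folds_rank_stratified(rnorm(10), 10, seed = 1)),
                   1:10)
  v <- rnorm(127)
  f <- make_folds_rank_stratified(v, 10, seed = 3)
  expect_identical(sort(unique(f)), 1:10)
  sizes <- as.integer(table(f))
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_identical(sum(sizes), 127L)
  # each fold's mean rank stays within +/- k of the global mean rank
  mean_ranks <- tapply(rank(v), f, mean)
  expect_lt(max(abs(mean_ranks - mean(rank(v)))), 10)
  # determinism and error handling
  expect_identical(f, make_folds_rank_stratified(v, 10, seed = 3))
  expect_error(make_folds_rank_stratified(rnorm(5), 10), "at least")
})

test_that("coef_reg = 1, coef_imp = 0 reduces to a plain random forest", {
  set.seed(2)
  x <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("d", 1:8)))
  y <- x[, 1] - 0.5 * x[, 2] + rnorm(60, 0, 0.2)
  hyper <- rrf_hyperparams(mtry = 3, coef_reg = 1, coef_imp = 0,
                           n_trees = 100)
  m <- train_rrf(x, y, hyper, seed = 7)
  # same construction by hand: plain forest on the centered response
  plain <- ranger::ranger(x = as.data.frame(x), y = y - mean(y),
                          num.trees = 100, mtry = 3, min.node.size = 5,
                          importance = "permutation", seed = 7,
                          num.threads = 1)
  expect_equal(predict(m, x),
               mean(y) + predict(plain, as.data.frame(x),
                                 num.threads = 1)$predictions,
               tolerance = 1e-12)
  expect_true(all(m$lambda == 1))
})

test_that("the forest interpolates a noiseless clustered signal exactly", {
  set.seed(7)
  x1 <- rep(c(0, 1), each = 24)
  x <- cbind(matrix(rnorm(48 * 9), 48, 9), x1)
  colnames(x) <- paste0("d", 1:10)
  y <- 10 * x1
  hyper <- rrf_hyperparams(mtry = 10, n_trees = 300, min_node = 1)
  m <- train_rrf(x, y, hyper, seed = 5)
  expect_lt(sqrt(mean((predict(m, x) - y)^2)), 1e-8)
  # column order invariance (statistically exact in this regime)
  perm <- c(4, 2, 9, 1, 10, 3, 7, 5, 8, 6)
  m2 <- train_rrf(x[, perm], y, hyper, seed = 5)
  expect_equal(predict(m2, x[, perm]), predict(m, x), tolerance = 1e-8)
  expect_true("d10" %in% m$used_features)
})

test_that("guided regularization surfaces the planted descriptors", {
  hits <- vapply(1:5, function(s) {
    ds <- generate_dataset(synth_config(seed = s))
    m <- train_rrf(ds$descriptor_matrix, ds$truth$log_rf,
                   rrf_hyperparams(mtry = 86, coef_reg = 1, coef_imp = 0.5,
                                   n_trees = 200),
                   seed = 100 + s, compute_used = FALSE)
    top10 <- order(m$importances, decreasing = TRUE)[1:10]
    sum(ds$informative %in% top10)
  }, 0)
  expect_gte(mean(hits), 4)
})

test_that("mtry beyond the descriptor count is rejected", {
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(train_rrf(x, rnorm(10), rrf_hyperparams(mtry = 5)), "mtry")
})

test_that("hyperparameter tuning picks the better model deterministically", {
  g1 <- data.frame(mtry = 4, coef_reg = 0.7, coef_imp = 0.5)
  set.seed(8)
  x <- matrix(rnorm(120 * 40), 120, 40,
              dimnames = list(NULL, paste0("d", 1:40)))
  y <- rowSums(x) + rnorm(120, 0, 0.5)
  single <- tune_hyperparameters(x, y, g1, n_trees = 50, seed = 2)
  expect_equal(single$best$mtry, 4L)
  expect_equal(single$best$coef_imp, 0.5)
  # dense signal: a plain forest must beat heavy feature regularization
  g2 <- data.frame(mtry = c(13, 13), coef_reg = c(1, 0.01),
                   coef_imp = c(0, 0))
  tuned <- tune_hyperparameters(x, y, g2, n_trees = 200, seed = 9)
  expect_equal(tuned$best$coef_reg, 1)
  tuned_again <- tune_hyperparameters(x, y, g2, n_trees = 200, seed = 9)
  expect_identical(tuned$results, tuned_again$results)
})

test_that("out-of-fold predictions honor the partition", {
  ds <- generate_dataset(synth_config(n_chemicals = 60, n_descriptors = 15,
                                      n_informative = 3,
                                      sigma_instrument = 0, seed = 31))
  y <- ds$truth$log_rf
  folds <- make_folds_rank_stratified(y, 5, seed = 31)
  hyper <- rrf_hyperparams(mtry = 15, n_trees = 150)
  oof <- cross_validated_predictions(ds$descriptor_matrix, y, hyper, folds,
                                     seed = 31)
  expect_false(anyNA(oof))
  expect_length(oof, 60)
  # poisoning: corrupting fold 2's responses cannot touch fold 2's predictions
  y_poison <- y
  y_poison[folds == 2] <- 999
  oof_p <- cross_validated_predictions(ds$descriptor_matrix, y_poison,
                                       hyper, folds, seed = 31)
  expect_equal(oof_p[folds == 2], oof[folds == 2], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(oof_p[folds == 1], oof[folds == 1])))
})

test_that("cross-validation recovers a strong noiseless signal", {
  ds <- generate_dataset(synth_config(n_descriptors = 15, n_informative = 3,
                                      sigma_instrument = 0, seed = 31))
  y <- ds$truth$log_rf
  folds <- make_folds_rank_stratified(y, 10, seed = 31)
  oof <- cross_validated_predictions(ds$descriptor_matrix, y,
                                     rrf_hyperparams(mtry = 15, n_trees = 300),
                                     folds, seed = 31)
  expect_gte(cor(oof, y, method = "spearman"), 0.9)
  # constant response: every prediction equals the constant
  yc <- rep(5, 127)
  oof_c <- cross_validated_predictions(
    ds$descriptor_matrix, yc, rrf_hyperparams(mtry = 5, n_trees = 30),
    make_folds_rank_stratified(yc, 5, seed = 1), seed = 2)
  expect_equal(oof_c, yc, tolerance = 1e-12)
})
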