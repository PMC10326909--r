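#' Regularized random forest hyperparameters
#'
#' @param mtry Number of descriptors sampled per split.
#' @param coef_reg Base gain penalty in (0, 1] applied to descriptors not yet
#'   used anywhere in the forest; 1 disables the penalty.
#' @param coef_imp Importance-guidance weight in \[0, 1\]: the effective
#'   penalty for a new descriptor `j` is
#'   `(1 - coef_imp) * coef_reg + coef_imp * imp_j`, where `imp_j` is the
#'   descriptor's normalized importance (max = 1) from a preliminary
#'   unregularized forest.
#' @param n_trees Number of trees.
#' @param min_node Minimal node size.
#' @return Object of class `rrf_hyperparams`.
#' @export
rrf_hyperparams <- function(mtry, coef_reg = 1.0, coef_imp = 0.0,
                            n_trees = 500, min_node = 5) {
  stopifnot(mtry >= 1, coef_reg > 0, coef_reg <= 1,
            coef_imp >= 0, coef_imp <= 1, n_trees >= 1, min_node >= 1)
  structure(list(mtry = as.integer(mtry), coef_reg = coef_reg,
                 coef_imp = coef_imp, n_trees = as.integer(n_trees),
                 min_node = as.integer(min_node)),
            class = "rrf_hyperparams")
}

#' Rank-stratified cross-validation folds
#'
#' Assigns chemicals to `k` folds so that each fold spans the whole response
#' distribution: chemicals are ordered by the rank of `values` and, within
#' each consecutive block of `k` ranks, fold labels are a seeded permutation
#' of `1:k` (the trailing partial block receives a random subset). Fold
#' sizes differ by at most one.
#'
#' @param values Per-chemical responses (e.g. log10 RF).
#' @param k Number of folds, default 10.
#' @param seed RNG seed.
#' @return Integer vector of fold indices in `1:k`, aligned with `values`.
#' @export
make_folds_rank_stratified <- function(values, k = 10, seed = 1) {
  n <- length(values)
  if (n < k) stop("need at least k observations")
  ord <- order(rank(values, ties.method = "first"))
  fold_of <- integer(n)
  rng <- .seeded_rng(seed)
  pos <- 1L
  while (pos <= n) {
    block <- ord[pos:min(pos + k - 1L, n)]
    labels <- rng$sample(k, length(block))
    fold_of[block] <- labels
    pos <- pos + k
  }
  fold_of
}

# Local RNG helper: isolates package RNG use from the caller's .Random.seed.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    expr_fun()
  }
  list(sample = function(k, size) run(function() sample.int(k, size)),
       draw_int = function() run(function() sample.int(.Machine$integer.max, 1L)))
}

#' Train a regularized (guided) random forest
#'
#' Fits a bootstrap ensemble of regression trees with variance-reduction
#' split gain in which the gain of a descriptor not yet used anywhere in the
#' forest is multiplied by
#' `lambda_j = (1 - coef_imp) * coef_reg + coef_imp * imp_j`; descriptors
#' already in the forest's used set are unpenalized. `imp_j` is the impurity
#' importance from a preliminary unregularized forest, normalized to max 1
#' (only fitted when `coef_imp > 0`). Permutation importances of the final
#' forest are computed on out-of-bag samples.
#'
#' @param x Numeric descriptor matrix (chemicals x descriptors), column
#'   names required.
#' @param y Response: per-chemical log10 RF (native instrument model) or
#'   log10 IE.
#' @param hyper An [rrf_hyperparams()].
#' @param seed RNG seed for bootstrap and feature subsampling.
#' @param compute_used Extract the set of descriptors split on anywhere in
#'   the forest (walks every tree; skipped inside cross-validation loops for
#'   speed).
#' @return Object of class `ie_model`: list with `fit` (the underlying
#'   ranger forest), `hyper`, `lambda` (per-descriptor penalty),
#'   `importances` (permutation, out-of-bag), `used_features` (descriptor
#'   names split on anywhere in the forest), `seed`.
#' @export
train_rrf <- function(x, y, hyper, seed = 1, compute_used = TRUE) {
  stopifnot(inherits(hyper, "rrf_hyperparams"), is.matrix(x),
            !is.null(colnames(x)), length(y) == nrow(x))
  p <- ncol(x)
  if (hyper$mtry > p) {
    stop("mtry (", hyper$mtry, ") exceeds the number of descriptors (", p, ")")
  }
  df <- as.data.frame(x)
  # the response is centered before fitting: the regularized split-gain
  # comparison is offset-sensitive, and log RF values live around 16, far
  # from zero; the mean is added back at prediction time
  y_center <- mean(y)
  y <- y - y_center
  lambda <- rep(hyper$coef_reg, p)
  if (hyper$coef_imp > 0) {
    prelim <- ranger::ranger(x = df, y = y, num.trees = hyper$n_trees,
                             mtry = hyper$mtry,
                             min.node.size = hyper$min_node,
                             importance = "impurity",
                             seed = seed, num.threads = 1)
    imp <- prelim$variable.importance
    imp_norm <- if (max(imp) > 0) pmax(imp, 0) / max(imp) else rep(1, p)
    lambda <- (1 - hyper$coef_imp) * hyper$coef_reg +
      hyper$coef_imp * imp_norm
  }
  regularize <- any(lambda < 1)
  fit <- ranger::ranger(
    x = df, y = y, num.trees = hyper$n_trees, mtry = hyper$mtry,
    min.node.size = hyper$min_node, importance = "permutation",
    regularization.factor = if (regularize) lambda else 1,
    regularization.usedepth = FALSE,
    seed = seed, num.threads = 1)
  used <- if (compute_used) {
    unique(unlist(lapply(seq_len(fit$num.trees), function(i) {
      info <- ranger::treeInfo(fit, i)
      info$splitvarName[!info$terminal]
    })))
  } else NULL
  structure(list(fit = fit, hyper = hyper,
                 lambda = stats::setNames(lambda, colnames(x)),
                 importances = fit$variable.importance,
                 used_features = used, y_center = y_center, seed = seed),
            class = "ie_model")
}

#' @export
predict.ie_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  object$y_center +
    stats::predict(object$fit, data = newdata, num.threads = 1)$predictions
}

#' @export
print.ie_model <- function(x, ...) {
  cat(sprintf(
    "<ie_model> %d trees, mtry = %d, coef_reg = %.2f, coef_imp = %.2f; %d/%d descriptors used\n",
    x$hyper$n_trees, x$hyper$mtry, x$hyper$coef_reg, x$hyper$coef_imp,
    length(x$used_features), length(x$lambda)))
  invisible(x)
}

#' Out-of-fold cross-validated predictions
#'
#' For each fold, a forest is trained on all other folds and used to predict
#' the held-out chemicals; every chemical receives exactly one prediction,
#' never from a model trained on its own fold.
#'
#' @param x Descriptor matrix.
#' @param y Response vector.
#' @param hyper An [rrf_hyperparams()].
#' @param folds Integer fold assignment from
#'   [make_folds_rank_stratified()].
#' @param seed Base seed; fold `f` trains with seed `seed + f`.
#' @return Numeric vector of out-of-fold predictions aligned with `y`.
#' @export
cross_validated_predictions <- function(x, y, hyper, folds, seed = 1) {
  stopifnot(length(folds) == length(y), all(folds >= 1))
  preds <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    model <- train_rrf(x[!hold, , drop = FALSE], y[!hold], hyper,
                       seed = seed + f, compute_used = FALSE)
    preds[hold] <- predict(model, x[hold, , drop = FALSE])
  }
  preds
}

#' Tune hyperparameters by repeated rank-stratified cross-validation
#'
#' Evaluates every grid point by mean validation RMSE over `n_folds`-fold
#' cross-validation repeated `n_repeats` times (2 x 2 by default), with
#' rank-stratified folds, and returns the grid row with the lowest mean RMSE
#' (first row on ties). Deterministic given `seed`.
#'
#' @param x Descriptor matrix.
#' @param y Response vector.
#' @param grid data.frame with columns `mtry`, `coef_reg`, `coef_imp` and
#'   optionally `n_trees`, `min_node`.
#' @param n_folds,n_repeats Cross-validation scheme (default 2-fold, 2
#'   repeats).
#' @param n_trees,min_node Defaults for grid rows lacking those columns.
#' @param seed RNG seed.
#' @return List with `best` (an [rrf_hyperparams()]), `results` (grid with a
#'   `rmse` column).
#' @export
tune_hyperparameters <- function(x, y, grid, n_folds = 2, n_repeats = 2,
                                 n_trees = 500, min_node = 5, seed = 1) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            all(c("mtry", "coef_reg", "coef_imp") %in% names(grid)))
  rmse <- matrix(NA_real_, nrow(grid), n_repeats * n_folds)
  for (r in seq_len(n_repeats)) {
    folds <- make_folds_rank_stratified(y, k = n_folds, seed = seed + 1000L * r)
    for (g in seq_len(nrow(grid))) {
      hyper <- rrf_hyperparams(
        mtry = grid$mtry[g], coef_reg = grid$coef_reg[g],
        coef_imp = grid$coef_imp[g],
        n_trees = if ("n_trees" %in% names(grid)) grid$n_trees[g] else n_trees,
        min_node = if ("min_node" %in% names(grid)) grid$min_node[g] else min_node)
      for (f in seq_len(n_folds)) {
        hold <- folds == f
        model <- train_rrf(x[!hold, , drop = FALSE], y[!hold], hyper,
                           seed = seed + 10L * r + f, compute_used = FALSE)
        pred <- predict(model, x[hold, , drop = FALSE])
        rmse[g, (r - 1L) * n_folds + f] <- sqrt(mean((pred - y[hold])^2))
      }
    }
  }
  results <- cbind(grid, rmse = rowMeans(rmse))
  best_row <- which.min(results$rmse)
  best <- rrf_hyperparams(
    mtry = grid$mtry[best_row], coef_reg = grid$coef_reg[best_row],
    coef_imp = grid$coef_imp[best_row],
    n_trees = if ("n_trees" %in% names(grid)) grid$n_trees[best_row] else n_trees,
    min_node = if ("min_node" %in% names(grid)) grid$min_node[best_row] else min_node)
  list(best = best, results = results)
}
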