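#' Near-zero-variance descriptor filter
#'
#' Flags descriptors whose value distribution is degenerate: a single unique
#' value, or a ratio of the most common to the second most common value of at
#' least `freq_cut` (default 19, i.e. 95/5).
#'
#' @param x Numeric matrix (chemicals x descriptors) with column names.
#' @param freq_cut Removal threshold on the frequency ratio.
#' @param kept_mask Optional logical vector of currently kept descriptors;
#'   defaults to all kept.
#' @return List with `kept_mask` (logical per descriptor) and
#'   `removal_reason` (character per descriptor, `""` or
#'   `"near_zero_variance"`).
#' @export
near_zero_variance_filter <- function(x, freq_cut = 19,
                                      kept_mask = rep(TRUE, ncol(x))) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, length(kept_mask) == ncol(x))
  reason <- character(ncol(x))
  for (j in which(kept_mask)) {
    tab <- sort(table(x[, j]), decreasing = TRUE)
    nzv <- length(tab) == 1L || (tab[1L] / tab[2L]) >= freq_cut
    if (nzv) {
      kept_mask[j] <- FALSE
      reason[j] <- "near_zero_variance"
    }
  }
  list(kept_mask = kept_mask, removal_reason = reason)
}

#' Pairwise-correlation descriptor filter
#'
#' Greedy removal of collinear descriptors on the absolute Pearson
#' correlation matrix: while any kept pair correlates above `cutoff`, the
#' most-correlated pair is located and the member with the larger mean
#' absolute correlation against all currently kept descriptors is removed
#' (correlations recomputed against the shrinking kept set; ties broken by
#' column order, the earlier column surviving). On return no kept pair
#' exceeds the cutoff.
#'
#' @param x Numeric matrix (chemicals x descriptors) with column names.
#' @param cutoff Absolute Pearson correlation threshold, default 0.75.
#' @param kept_mask Logical per descriptor, typically the output of
#'   [near_zero_variance_filter()].
#' @return List with `kept_mask` and `removal_reason` (`"correlated"` for
#'   descriptors removed here).
#' @export
correlation_filter <- function(x, cutoff = 0.75,
                               kept_mask = rep(TRUE, ncol(x))) {
  stopifnot(is.matrix(x), length(kept_mask) == ncol(x))
  reason <- character(ncol(x))
  kept <- which(kept_mask)
  while (length(kept) >= 2L) {
    cm <- abs(stats::cor(x[, kept, drop = FALSE]))
    diag(cm) <- 0
    top <- max(cm)
    if (top <= cutoff) break
    hit <- which(cm == top, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    # deterministic pair choice: smallest row index, then smallest column
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
    mean_abs <- (rowSums(cm) ) / (length(kept) - 1L)
    mi <- mean_abs[hit[1L]]; mj <- mean_abs[hit[2L]]
    drop_local <- if (mj >= mi) hit[2L] else hit[1L]  # tie: later column goes
    drop_col <- kept[drop_local]
    kept_mask[drop_col] <- FALSE
    reason[drop_col] <- "correlated"
    kept <- kept[-drop_local]
  }
  list(kept_mask = kept_mask, removal_reason = reason)
}

#' Apply both descriptor filters
#'
#' Near-zero-variance filter followed by the pairwise-correlation filter,
#' returning a `descriptor_matrix` object carrying the kept mask and a
#' removal log.
#'
#' @param x Numeric matrix (chemicals x descriptors), column names required.
#' @param freq_cut See [near_zero_variance_filter()].
#' @param cor_cutoff See [correlation_filter()].
#' @return Object of class `descriptor_matrix`: list with `values` (the full
#'   matrix), `chemical_ids`, `descriptor_names`, `kept_mask`,
#'   `removal_reason`, and `kept` (the filtered matrix).
#' @export
filter_descriptors <- function(x, freq_cut = 19, cor_cutoff = 0.75) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  nzv <- near_zero_variance_filter(x, freq_cut = freq_cut)
  cf <- correlation_filter(x, cutoff = cor_cutoff, kept_mask = nzv$kept_mask)
  reason <- ifelse(nzv$removal_reason != "", nzv$removal_reason,
                   cf$removal_reason)
  structure(list(
    values = x,
    chemical_ids = rownames(x),
    descriptor_names = colnames(x),
    kept_mask = cf$kept_mask,
    removal_reason = reason,
    kept = x[, cf$kept_mask, drop = FALSE]
  ), class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("<descriptor_matrix>", nrow(x$values), "chemicals x",
      ncol(x$values), "descriptors;", sum(x$kept_mask), "kept (",
      sum(x$removal_reason == "near_zero_variance"), "near-zero-variance,",
      sum(x$removal_reason == "correlated"), "correlated removed )\n")
  invisible(x)
}

#' Spearman correlation profile of descriptors vs log RF
#'
#' Tie-corrected Spearman rho of every kept descriptor against the
#' per-chemical log10 response factor, sorted by rho (descending); the
#' retention-time correlation is reported alongside when retention times are
#' given.
#'
#' @param x Numeric descriptor matrix (chemicals x descriptors) or a
#'   `descriptor_matrix` (its kept columns are used).
#' @param log_rf Per-chemical log10 RF, aligned with the rows of `x`.
#' @param retention_time Optional per-chemical retention times (minutes).
#' @return List with `profile` (data.frame: `descriptor`, `rho`, sorted
#'   descending) and `rt_rho` (Spearman rho of retention time vs log RF, or
#'   `NA`).
#' @export
spearman_profile <- function(x, log_rf, retention_time = NULL) {
  if (inherits(x, "descriptor_matrix")) x <- x$kept
  stopifnot(is.matrix(x), nrow(x) == length(log_rf))
  rho <- suppressWarnings(
    as.numeric(stats::cor(x, log_rf, method = "spearman")))
  prof <- data.frame(descriptor = colnames(x), rho = rho,
                     stringsAsFactors = FALSE)
  prof <- prof[order(-prof$rho), , drop = FALSE]
  rownames(prof) <- NULL
  rt_rho <- if (is.null(retention_time)) NA_real_ else {
    stats::cor(retention_time, log_rf, method = "spearman")
  }
  list(profile = prof, rt_rho = rt_rho)
}
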