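# Independent oracles used by the tests; deliberately brute-force and kept
# separate from the implementation paths they check.

# per-element isotopologue distributions over extra-nucleon shifts
iso_shift_dists <- list(
  C  = c(`0` = 0.9893,   `1` = 0.0107),
  H  = c(`0` = 0.999885, `1` = 0.000115),
  N  = c(`0` = 0.99636,  `1` = 0.00364),
  O  = c(`0` = 0.99757,  `1` = 0.00038, `2` = 0.00205),
  S  = c(`0` = 0.9499,   `1` = 0.0075,  `2` = 0.0425, `4` = 0.0001),
  P  = c(`0` = 1),
  F  = c(`0` = 1),
  Cl = c(`0` = 0.7576,   `2` = 0.2424),
  Br = c(`0` = 0.5069,   `2` = 0.4931),
  I  = c(`0` = 1)
)

convolve_shift <- function(a, b) {
  out <- numeric(0)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      key <- as.character(as.integer(names(a)[i]) + as.integer(names(b)[j]))
      out[key] <- (if (key %in% names(out)) out[[key]] else 0) + a[[i]] * b[[j]]
    }
  }
  out
}

# full isotopologue convolution; the monoisotopic peak is the zero-shift term
isotopologue_mono_oracle <- function(formula) {
  counts <- parse_formula(formula)
  dist <- c(`0` = 1)
  for (el in names(counts)) {
    for (r in seq_len(counts[[el]])) {
      dist <- convolve_shift(dist, iso_shift_dists[[el]])
    }
  }
  unname(dist[["0"]])
}

# exhaustive search over removal sets: all maximum-size column subsets with
# no absolute pairwise correlation above the cutoff
brute_max_keep <- function(x, cutoff = 0.75) {
  p <- ncol(x)
  for (size in p:1) {
    valid <- list()
    cb <- utils::combn(p, size)
    for (ci in seq_len(ncol(cb))) {
      s <- cb[, ci]
      cm <- abs(stats::cor(x[, s, drop = FALSE]))
      diag(cm) <- 0
      if (all(cm <= cutoff)) valid[[length(valid) + 1L]] <- s
    }
    if (length(valid) > 0L) return(valid)
  }
}

# tie-corrected Spearman by rank-then-Pearson
spearman_brute <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"), method = "pearson")
}

# small collinear instance family for correlation-filter cross-checks
make_cor_instance <- function(seed) {
  set.seed(seed)
  p <- sample(4:6, 1)
  z <- stats::rnorm(25)
  x <- sapply(seq_len(p), function(j) {
    if (j %% 2) z + stats::rnorm(25, 0, stats::runif(1, 0.2, 1.5))
    else stats::rnorm(25)
  })
  colnames(x) <- paste0("v", seq_len(p))
  x
}
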