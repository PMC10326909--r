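#' Monte Carlo study of calibrant-set selection
#'
#' For each calibrant count `k` and each repetition: sample `k` chemicals
#' without replacement as calibrants, fit the robust transfer line on their
#' (predicted log IE, measured log RF) pairs, convert the remaining (test
#' set) chemicals' predicted log IE values to response factors, quantify
#' them at all their calibration levels, and record the test-set median
#' error factor together with the calibrant retention-time and predicted
#' log IE ranges.
#'
#' @param log_ie_pred Named vector of predicted log10 IE per chemical.
#' @param log_rf_measured Named vector of measured log10 RF, same chemicals.
#' @param areas data.frame (`chemical_id`, `concentration`,
#'   `corrected_area`) of the quantification inputs, e.g. linear-range
#'   levels only; see [quantify_chemicals()].
#' @param retention_time Named vector of retention times (minutes).
#' @param k_values Calibrant counts to scan, default `5:20`.
#' @param n_rep Repetitions per `k`, default 200.
#' @param seed RNG seed.
#' @return data.frame of `MCSample` rows: `k`, `rep`, `rt_range`,
#'   `ie_range`, `median_ef`, plus `calibrant_ids` (comma-separated).
#' @export
run_mc_study <- function(log_ie_pred, log_rf_measured, areas,
                         retention_time, k_values = 5:20, n_rep = 200,
                         seed = 1) {
  ids <- names(log_ie_pred)
  stopifnot(!is.null(ids), setequal(ids, names(log_rf_measured)),
            setequal(ids, names(retention_time)))
  n <- length(ids)
  if (any(k_values >= n)) stop("k must be smaller than the number of chemicals")
  if (any(k_values < 2)) stop("k must be at least 2")
  areas$chemical_id <- as.character(areas$chemical_id)
  area_split <- split(seq_len(nrow(areas)), areas$chemical_id)
  rows <- vector("list", length(k_values) * n_rep)
  i <- 0L
  set.seed(seed)
  for (k in k_values) {
    for (rep_i in seq_len(n_rep)) {
      cal <- sample(ids, k)
      test <- setdiff(ids, cal)
      line <- fit_transfer(log_ie_pred[cal], log_rf_measured[cal])
      rf_pred <- stats::setNames(rf_from_ie(log_ie_pred[test], line), test)
      idx <- unlist(area_split[test], use.names = FALSE)
      qr <- quantify_chemicals(areas[idx, , drop = FALSE], rf_pred)
      i <- i + 1L
      rows[[i]] <- data.frame(
        k = k, rep = rep_i,
        rt_range = diff(range(retention_time[cal])),
        ie_range = diff(range(log_ie_pred[cal])),
        median_ef = stats::median(qr$error_factor),
        calibrant_ids = paste(cal, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate Monte Carlo calibrant-selection samples
#'
#' Summaries matching the three panels of the study: (a) per-`k` mean and SD
#' of the median error factor, with the SD also reported in log10 units
#' (sample SD of `log10(median EF)` across repetitions); (b) mean median EF
#' by calibrant retention-time-range quartile; (c) mean median EF by
#' predicted-log-IE-range quartile.
#'
#' @param samples data.frame from [run_mc_study()].
#' @return List of data.frames `by_k`, `by_rt_range`, `by_ie_range`.
#' @export
aggregate_mc <- function(samples) {
  stopifnot(nrow(samples) >= 1L)
  agg_k <- do.call(rbind, lapply(split(samples, samples$k), function(d) {
    data.frame(k = d$k[1L],
               mean_median_ef = mean(d$median_ef),
               sd_median_ef = stats::sd(d$median_ef),
               sd_log10_median_ef = stats::sd(log10(d$median_ef)))
  }))
  rownames(agg_k) <- NULL
  bin_by <- function(v, label) {
    br <- stats::quantile(v, probs = seq(0, 1, 0.25), names = FALSE)
    br <- unique(br)
    bin <- cut(v, breaks = br, include.lowest = TRUE)
    out <- do.call(rbind, lapply(split(samples$median_ef, bin), function(e) {
      data.frame(n = length(e), mean_median_ef = mean(e),
                 sd_log10_median_ef = stats::sd(log10(e)))
    }))
    out <- cbind(data.frame(bin = rownames(out), stringsAsFactors = FALSE), out)
    names(out)[1L] <- label
    rownames(out) <- NULL
    out
  }
  list(by_k = agg_k,
       by_rt_range = bin_by(samples$rt_range, "rt_range_bin"),
       by_ie_range = bin_by(samples$ie_range, "ie_range_bin"))
}
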