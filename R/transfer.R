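#' Robust calibration-transfer regression
#'
#' Fits `log10 RF = slope * log10 IE + intercept` by iteratively reweighted
#' least squares with Huber weights (tuning constant `k = 1.345`, scale
#' re-estimated each iteration as `median(|residual|)/0.6745`), mapping
#' relative predicted ionization efficiencies onto instrument-specific
#' response factors from a small set of calibration chemicals.
#'
#' @param log_ie_pred Predicted log10 IE per calibrant.
#' @param log_rf_measured Measured log10 RF per calibrant.
#' @param k_huber Huber tuning constant, default 1.345 (95% Gaussian
#'   efficiency).
#' @param max_iter Maximum IRLS iterations, default 50.
#' @param tol Relative coefficient-change convergence tolerance, default
#'   1e-8.
#' @return Object of class `transfer_line`: list with `slope`, `intercept`
#'   (log10 1/M), `robust_weights` in \[0, 1\], `n_points`, `converged`.
#' @export
fit_transfer <- function(log_ie_pred, log_rf_measured, k_huber = 1.345,
                         max_iter = 50, tol = 1e-8) {
  x <- as.numeric(log_ie_pred); y <- as.numeric(log_rf_measured)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("need at least 2 calibrants with finite values")
  if (diff(range(x)) == 0) stop("degenerate design: all log IE values identical")
  X <- cbind(1, x)
  beta <- stats::lm.fit(X, y)$coefficients
  w <- rep(1, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    s <- stats::median(abs(r)) / 0.6745
    if (s < 1e-12) { converged <- TRUE; w <- rep(1, n); break }
    w <- pmin(1, k_huber * s / abs(r))
    new_beta <- stats::lm.wfit(X, y, w)$coefficients
    if (max(abs(new_beta - beta)) <= tol * max(abs(beta), 1)) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
  }
  structure(list(slope = unname(beta[2L]), intercept = unname(beta[1L]),
                 robust_weights = as.numeric(w), n_points = n,
                 converged = converged),
            class = "transfer_line")
}

#' @export
print.transfer_line <- function(x, ...) {
  cat(sprintf("<transfer_line> log10 RF = %.4f * log10 IE + %.4f (n = %d%s)\n",
              x$slope, x$intercept, x$n_points,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Predicted response factor from predicted log IE
#'
#' @param log_ie_pred Predicted log10 IE (vectorized).
#' @param line A fitted [fit_transfer()] line.
#' @return Response factor in 1/M: `10^(slope * log_ie_pred + intercept)`.
#' @export
rf_from_ie <- function(log_ie_pred, line) {
  stopifnot(inherits(line, "transfer_line"))
  10^(line$slope * log_ie_pred + line$intercept)
}

#' Predict a concentration from a corrected peak area
#'
#' Inverse of the calibration model: `concentration = corrected area / RF`.
#'
#' @param corrected_area Isotope-corrected peak area.
#' @param rf Response factor, 1/M (> 0).
#' @return Concentration in mol/L.
#' @export
predict_concentration <- function(corrected_area, rf) {
  if (any(rf <= 0)) stop("rf must be > 0")
  corrected_area / rf
}

#' Symmetric fold error of a concentration prediction
#'
#' `max(predicted/spiked, spiked/predicted)`, which is always >= 1 and
#' treats over- and underestimation identically:
#' `log10(error_factor) = |log10 predicted - log10 spiked|`.
#'
#' @param predicted Predicted concentration, mol/L (> 0).
#' @param spiked True (spiked) concentration, mol/L (> 0).
#' @return Error factor >= 1 (vectorized).
#' @export
error_factor <- function(predicted, spiked) {
  if (any(predicted <= 0) || any(spiked <= 0)) {
    stop("concentrations must be > 0")
  }
  pmax(predicted / spiked, spiked / predicted)
}

#' Summarize concentration-prediction error factors
#'
#' Error factors are first aggregated per chemical (median over its
#' concentration levels); the summary reports the median and mean of those
#' per-chemical values and the fraction of chemicals whose error factor is
#' below 10 at every level.
#'
#' @param results data.frame with columns `chemical_id` and `error_factor`
#'   (one row per chemical x level), e.g. from [quantify_chemicals()].
#' @return List with `median_ef`, `mean_ef`, `frac_under_10`, `n_chemicals`.
#' @export
summarize_errors <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("chemical_id", "error_factor") %in% names(results)))
  per_chem <- tapply(results$error_factor, results$chemical_id, stats::median)
  all_under <- tapply(results$error_factor, results$chemical_id,
                      function(e) all(e < 10))
  list(median_ef = unname(stats::median(per_chem)),
       mean_ef = unname(mean(per_chem)),
       frac_under_10 = unname(mean(all_under)),
       n_chemicals = length(per_chem))
}

#' Quantify chemicals from areas and predicted response factors
#'
#' @param areas data.frame with columns `chemical_id`, `concentration`
#'   (spiked, mol/L) and `corrected_area` (one row per chemical x level
#'   x replicate or per chemical x level).
#' @param rf Named vector of predicted response factors (1/M) keyed by
#'   chemical id.
#' @return data.frame of `QuantResult` rows: `chemical_id`, `level`
#'   (spiked mol/L), `predicted_conc` (mol/L), `error_factor`.
#' @export
quantify_chemicals <- function(areas, rf) {
  stopifnot(all(c("chemical_id", "concentration", "corrected_area") %in%
                  names(areas)))
  r <- rf[as.character(areas$chemical_id)]
  if (any(is.na(r))) {
    stop("missing response factor for chemical(s): ",
         paste(unique(areas$chemical_id[is.na(r)]), collapse = ", "))
  }
  pred <- predict_concentration(areas$corrected_area, as.numeric(r))
  data.frame(chemical_id = areas$chemical_id,
             level = areas$concentration,
             predicted_conc = pred,
             error_factor = error_factor(pred, areas$concentration),
             stringsAsFactors = FALSE)
}
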