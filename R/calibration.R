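#' Construct a calibration series
#'
#' Bundles replicate peak areas per concentration level for one analyte.
#'
#' @param chemical_id Identifier of the analyte.
#' @param concentrations Strictly increasing molar concentrations (mol/L),
#'   one per level.
#' @param areas Matrix (levels x replicates) or list of numeric vectors of
#'   raw peak areas; at least one replicate per level.
#' @return An object of class `calibration_series`.
#' @export
calibration_series <- function(chemical_id, concentrations, areas) {
  if (is.matrix(areas)) areas <- split(areas, row(areas))
  stopifnot(length(concentrations) == length(areas))
  if (any(diff(concentrations) <= 0) || any(concentrations <= 0)) {
    stop("concentrations must be positive and strictly increasing")
  }
  if (any(vapply(areas, length, 1L) < 1L)) {
    stop("every level needs at least one replicate area")
  }
  structure(
    list(chemical_id = chemical_id,
         concentrations = as.numeric(concentrations),
         areas = lapply(areas, as.numeric)),
    class = "calibration_series"
  )
}

#' @export
print.calibration_series <- function(x, ...) {
  cat("<calibration_series>", x$chemical_id, "-", length(x$concentrations),
      "levels,", length(x$areas[[1]]), "replicate(s) at level 1\n")
  invisible(x)
}

# Relative residuals of a weighted least squares fit of mean area vs
# concentration on the given level indices. Weights 1/conc^2 reflect the
# multiplicative (constant relative SD) noise of peak areas, so every level
# is judged on the same relative scale and a saturated plateau cannot
# masquerade as a flat "linear" fit; residuals are scaled by the fitted
# value (floored away from 0 so a near-zero fit cannot blow up the ratio).
.rel_residuals <- function(conc, mean_area, idx) {
  w <- 1 / conc[idx]^2
  fit <- stats::lm.wfit(cbind(1, conc[idx]), mean_area[idx], w)
  fitted <- mean_area[idx] - fit$residuals
  denom <- pmax(abs(fitted), 1e-12 * max(abs(mean_area[idx]), 1e-300))
  abs(fit$residuals) / denom
}

#' Detect the linear range of a calibration series
#'
#' Automated surrogate for manual residual inspection of a calibration graph.
#' Levels whose replicate relative standard deviation exceeds
#' `replicate_rsd_tol` are excluded up front. Then the retained (contiguous)
#' range is pruned greedily: a relative-error weighted least squares line
#' (weights `1/concentration^2`, matching the multiplicative area noise) of
#' mean area vs concentration is fit on the current levels and, while the
#' worst relative residual exceeds `rel_residual_tol` and more than three
#' levels remain, the
#' endpoint level with the worse relative residual is dropped (the higher
#' concentration on ties, since saturation at the top of the range is the
#' expected failure mode). A chemical must keep at least three levels whose
#' worst relative residual is within tolerance; otherwise it has no linear
#' range.
#'
#' @param series A [calibration_series()].
#' @param rel_residual_tol Maximum tolerated relative residual (fraction of
#'   the fitted value), default 0.2.
#' @param replicate_rsd_tol Maximum tolerated replicate RSD per level,
#'   default 0.3 (the reproducibility bound of the underlying experiment).
#' @param corrected_means Optional precomputed isotope-corrected mean areas
#'   per level; defaults to the plain replicate means (the isotope correction
#'   is a common factor and does not affect residual ratios).
#' @return Integer vector of retained level indices (into
#'   `series$concentrations`), or `integer(0)` if no linear range exists.
#' @export
detect_linear_range <- function(series, rel_residual_tol = 0.2,
                                replicate_rsd_tol = 0.3,
                                corrected_means = NULL) {
  stopifnot(inherits(series, "calibration_series"))
  if (rel_residual_tol <= 0 || rel_residual_tol > 1 ||
      replicate_rsd_tol <= 0 || replicate_rsd_tol > 1) {
    stop("tolerances must be in (0, 1]")
  }
  conc <- series$concentrations
  n <- length(conc)
  if (n < 3L) return(integer(0))
  mean_area <- if (is.null(corrected_means)) {
    vapply(series$areas, mean, 0)
  } else {
    corrected_means
  }
  rsd <- vapply(series$areas, function(a) {
    if (length(a) < 2L || mean(a) == 0) 0 else stats::sd(a) / abs(mean(a))
  }, 0)
  keep <- which(rsd <= replicate_rsd_tol)
  if (length(keep) < 3L) return(integer(0))
  repeat {
    rr <- .rel_residuals(conc, mean_area, keep)
    if (max(rr) <= rel_residual_tol) return(keep)
    if (length(keep) <= 3L) return(integer(0))
    # endpoints only: the linear range stays contiguous within the kept set
    lo <- rr[1L]; hi <- rr[length(rr)]
    drop_at <- if (hi >= lo) length(keep) else 1L
    keep <- keep[-drop_at]
  }
}

#' Estimate an isotope-corrected response factor
#'
#' Computes the response factor (RF) of an analyte: the slope, in 1/M, of the
#' ordinary least squares line (with intercept) of isotope-corrected replicate
#' peak areas vs molar concentration over the detected linear range. The
#' intercept absorbs baseline offsets; the slope alone is the RF.
#'
#' @param series A [calibration_series()].
#' @param formula Molecular formula of the analyte (string or named counts),
#'   used for the isotope correction. `NULL` skips the correction
#'   (factor 1).
#' @param rel_residual_tol,replicate_rsd_tol Passed to
#'   [detect_linear_range()].
#' @return An object of class `rf_estimate`: list with `chemical_id`, `rf`
#'   (1/M), `intercept`, `linear_levels`, `n_linear`, `max_rel_residual`,
#'   `isotope_correction_factor` (>= 1), `ok` (logical) and `flag`
#'   (`""`, `"no_linear_range"` or `"nonpositive_slope"`).
#' @export
estimate_response_factor <- function(series, formula = NULL,
                                     rel_residual_tol = 0.2,
                                     replicate_rsd_tol = 0.3) {
  stopifnot(inherits(series, "calibration_series"))
  frac <- if (is.null(formula)) 1.0 else monoisotopic_fraction(formula)
  corr_areas <- lapply(series$areas, correct_area, fraction = frac)
  corr_means <- vapply(corr_areas, mean, 0)
  lin <- detect_linear_range(series, rel_residual_tol, replicate_rsd_tol,
                             corrected_means = corr_means)
  res <- list(chemical_id = series$chemical_id, rf = NA_real_,
              intercept = NA_real_, linear_levels = lin,
              n_linear = length(lin), max_rel_residual = NA_real_,
              isotope_correction_factor = 1 / frac,
              ok = FALSE, flag = "")
  class(res) <- "rf_estimate"
  if (length(lin) < 3L) {
    res$flag <- "no_linear_range"
    return(res)
  }
  x <- rep(series$concentrations[lin], vapply(corr_areas[lin], length, 1L))
  y <- unlist(corr_areas[lin], use.names = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  res$intercept <- unname(fit$coefficients[1L])
  res$rf <- unname(fit$coefficients[2L])
  res$max_rel_residual <- max(.rel_residuals(series$concentrations,
                                             corr_means, lin))
  if (!is.finite(res$rf) || res$rf <= 0) {
    res$flag <- "nonpositive_slope"
    return(res)
  }
  res$ok <- TRUE
  res
}

#' @export
print.rf_estimate <- function(x, ...) {
  cat("<rf_estimate>", x$chemical_id,
      if (x$ok) sprintf("RF = %.3g 1/M over %d levels", x$rf, x$n_linear)
      else paste("flagged:", x$flag), "\n")
  invisible(x)
}

#' Estimate response factors for a whole calibration table
#'
#' @param series_list List of [calibration_series()].
#' @param formulas Optional named list/vector of molecular formulas keyed by
#'   chemical id.
#' @param ... Passed to [estimate_response_factor()].
#' @return data.frame with one row per chemical: `chemical_id`, `rf_M_inv`,
#'   `log10_rf`, `n_linear`, `isotope_correction_factor`, `ok`, `flag`.
#' @export
estimate_response_factors <- function(series_list, formulas = NULL, ...) {
  rows <- lapply(series_list, function(s) {
    f <- if (is.null(formulas)) NULL else formulas[[s$chemical_id]]
    e <- estimate_response_factor(s, formula = f, ...)
    data.frame(chemical_id = e$chemical_id,
               rf_M_inv = e$rf,
               log10_rf = ifelse(e$ok, log10(e$rf), NA_real_),
               n_linear = e$n_linear,
               isotope_correction_factor = e$isotope_correction_factor,
               ok = e$ok, flag = e$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
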