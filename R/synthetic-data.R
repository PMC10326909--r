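#' Configuration for the synthetic SFC calibration data generator
#'
#' Defaults emulate the structure of a 127-chemical SFC/ESI/HRMS calibration
#' experiment: triplicate levels geometrically spaced from 12.2 to 1750
#' nmol/L with a saturating linear range, response factors spanning four
#' decades (anchored at 4.06e14 to 2.70e18 1/M through a unit-slope
#' instrument map on the log10 ionization-efficiency scale), a sparse
#' dependence of log IE on a handful of informative descriptors inside a
#' collinear descriptor block structure, and retention times weakly
#' anticorrelated with log RF.
#'
#' @param n_chemicals Number of chemicals (default 127).
#' @param n_descriptors Number of molecular descriptors (default 200).
#' @param n_informative Number of descriptors that truly drive log IE
#'   (default 5).
#' @param beta_scale Scale (SD) of the raw informative coefficients, log10
#'   IE units per standardized descriptor; only their relative magnitudes
#'   matter because log IE is affinely rescaled to `ie_range_target`.
#' @param ie_range_target `(low, high)` span of true log10 IE.
#' @param instrument_slope,instrument_intercept Linear map from log10 IE to
#'   log10 RF (intercept in log10 1/M units).
#' @param sigma_instrument SD of the log10 RF noise around the instrument
#'   map (log10 units).
#' @param sigma_area Relative SD of multiplicative peak-area noise.
#' @param conc_levels Strictly increasing molar concentrations (mol/L);
#'   default 8 geometric levels from 12.2 to 1750 nmol/L.
#' @param n_replicates Replicates per level (default 3).
#' @param saturation_quantile Fraction of levels inside the linear range
#'   (default 0.75, i.e. the top quarter of levels saturates).
#' @param n_factors Latent factors behind the descriptor correlation
#'   structure (default 10).
#' @param rt_anticorrelation Target (negative) correlation between
#'   retention time and log RF, default -0.29.
#' @param seed RNG seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_chemicals = 127,
                         n_descriptors = 200,
                         n_informative = 5,
                         beta_scale = 1,
                         ie_range_target = c(0, log10(2.70e18 / 4.06e14)),
                         instrument_slope = 1,
                         instrument_intercept = log10(4.06e14),
                         sigma_instrument = 0.15,
                         sigma_area = 0.1,
                         conc_levels = 12.2e-9 * (1750 / 12.2)^(0:7 / 7),
                         n_replicates = 3,
                         saturation_quantile = 0.75,
                         n_factors = 10,
                         rt_anticorrelation = -0.29,
                         seed = 1) {
  cfg <- list(n_chemicals = as.integer(n_chemicals),
              n_descriptors = as.integer(n_descriptors),
              n_informative = as.integer(n_informative),
              beta_scale = beta_scale,
              ie_range_target = as.numeric(ie_range_target),
              instrument_slope = instrument_slope,
              instrument_intercept = instrument_intercept,
              sigma_instrument = sigma_instrument,
              sigma_area = sigma_area,
              conc_levels = as.numeric(conc_levels),
              n_replicates = as.integer(n_replicates),
              saturation_quantile = saturation_quantile,
              n_factors = as.integer(n_factors),
              rt_anticorrelation = rt_anticorrelation,
              seed = as.integer(seed))
  if (cfg$n_informative > cfg$n_descriptors) {
    stop("n_informative must not exceed n_descriptors")
  }
  if (cfg$sigma_instrument < 0 || cfg$sigma_area < 0) {
    stop("noise SDs must be >= 0")
  }
  if (length(cfg$ie_range_target) != 2L ||
      cfg$ie_range_target[2L] <= cfg$ie_range_target[1L]) {
    stop("ie_range_target must be (low, high) with high > low")
  }
  if (any(cfg$conc_levels <= 0) || any(diff(cfg$conc_levels) <= 0)) {
    stop("conc_levels must be positive and strictly increasing")
  }
  if (cfg$saturation_quantile <= 0 || cfg$saturation_quantile > 1) {
    stop("saturation_quantile must be in (0, 1]")
  }
  if (length(cfg$conc_levels) < 3L) stop("need at least 3 levels")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic SFC calibration dataset
#'
#' Draws a complete dataset with known ground truth:
#' descriptors follow a latent factor model (each descriptor loads on one of
#' `n_factors` factors, alternating tight and loose idiosyncratic noise, so
#' realistic collinearity exists for the correlation filter); true log10 IE
#' is a linear combination of `n_informative` randomly chosen descriptors,
#' affinely rescaled to exactly span `ie_range_target`; true log10 RF is
#' `instrument_intercept + instrument_slope * log IE` plus Gaussian noise;
#' peak areas are `10^logRF * conc * monoisotopic_fraction * (1 + noise)`
#' within the linear range and plateau hard at the top-linear-level area
#' above it; molecular formulas are random C/H/N/O compositions; retention
#' times are drawn weakly anticorrelated with log RF. Fully reproducible
#' from the config seed.
#'
#' @param config A [synth_config()].
#' @return Object of class `synthetic_dataset`: list with `chemicals`
#'   (data.frame: `chemical_id`, `name`, `formula`, `retention_time`),
#'   `descriptor_matrix` (chemicals x descriptors, named), `calibration`
#'   (list of [calibration_series()]), `truth` (data.frame: `chemical_id`,
#'   `log_ie`, `log_rf`, `top_linear_level`, `top_linear_conc`),
#'   `informative` (descriptor indices), `instrument` (slope, intercept),
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_chemicals
  p <- config$n_descriptors
  set.seed(config$seed)
  ids <- sprintf("chem%03d", seq_len(n))

  # correlated descriptors: the bulk load on shared latent factors with
  # alternating tight/loose idiosyncratic noise (collinear blocks for the
  # correlation filter); the informative columns are drawn independently so
  # the descriptor -> log IE dependence stays sparse
  informative <- sort(sample(p, config$n_informative))
  fac <- matrix(stats::rnorm(n * config$n_factors), n, config$n_factors)
  block <- sample(rep_len(seq_len(config$n_factors), p))
  noise_sd <- ifelse(seq_len(p) %% 2L == 0L, 0.3, 1.0)
  X <- vapply(seq_len(p), function(j) {
    if (j %in% informative) {
      stats::rnorm(n)
    } else {
      fac[, block[j]] + stats::rnorm(n, 0, noise_sd[j])
    }
  }, numeric(n))
  X <- matrix(X, nrow = n, ncol = p)
  if (n > 1L) {
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
  }
  dimnames(X) <- list(ids, sprintf("d%03d", seq_len(p)))

  beta <- config$beta_scale *
    sample(c(-1, 1), config$n_informative, replace = TRUE) *
    stats::runif(config$n_informative, 0.7, 1.3)
  raw <- drop(X[, informative, drop = FALSE] %*% beta)
  lo <- config$ie_range_target[1L]; hi <- config$ie_range_target[2L]
  if (n == 1L) {
    log_ie <- mean(c(lo, hi))
  } else {
    if (diff(range(raw)) == 0) stop("degenerate ionization-efficiency signal")
    log_ie <- lo + (raw - min(raw)) / diff(range(raw)) * (hi - lo)
  }
  log_rf <- config$instrument_intercept + config$instrument_slope * log_ie +
    stats::rnorm(n, 0, config$sigma_instrument)

  # retention times weakly anticorrelated with log RF, mapped into the
  # 1-11 min elution window of the default gradient
  z <- if (n > 1L && stats::sd(log_rf) > 0) as.numeric(scale(log_rf)) else rep(0, n)
  rho <- config$rt_anticorrelation
  rt_raw <- rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  rt <- 1 + 10 * (rt_raw - min(rt_raw)) / max(diff(range(rt_raw)), 1e-12)

  nc <- sample(5:30, n, replace = TRUE)
  nh <- pmax(2L, round(1.8 * nc) + sample(-3:3, n, replace = TRUE))
  nn <- sample(0:3, n, replace = TRUE)
  no <- sample(0:5, n, replace = TRUE)
  formulas <- sprintf("C%dH%d%s%s", nc, nh,
                      ifelse(nn > 0, paste0("N", nn), ""),
                      ifelse(no > 0, paste0("O", no), ""))

  n_levels <- length(config$conc_levels)
  top <- max(3L, ceiling(config$saturation_quantile * n_levels))
  c_top <- config$conc_levels[top]
  mono <- vapply(formulas, monoisotopic_fraction, 0)

  calibration <- vector("list", n)
  for (i in seq_len(n)) {
    c_eff <- pmin(config$conc_levels, c_top)
    mean_area <- 10^log_rf[i] * c_eff * mono[i]
    noise <- matrix(stats::rnorm(n_levels * config$n_replicates, 0,
                                 config$sigma_area),
                    n_levels, config$n_replicates)
    areas <- mean_area * (1 + noise)
    calibration[[i]] <- calibration_series(ids[i], config$conc_levels,
                                           lapply(seq_len(n_levels),
                                                  function(l) areas[l, ]))
  }
  names(calibration) <- ids

  structure(list(
    chemicals = data.frame(chemical_id = ids,
                           name = paste("compound", seq_len(n)),
                           formula = formulas,
                           retention_time = rt,
                           stringsAsFactors = FALSE),
    descriptor_matrix = X,
    calibration = calibration,
    truth = data.frame(chemical_id = ids, log_ie = log_ie, log_rf = log_rf,
                       top_linear_level = top, top_linear_conc = c_top,
                       stringsAsFactors = FALSE),
    informative = informative,
    instrument = c(slope = config$instrument_slope,
                   intercept = config$instrument_intercept),
    config = config
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", nrow(x$chemicals), "chemicals,",
      ncol(x$descriptor_matrix), "descriptors,",
      length(x$config$conc_levels), "levels x", x$config$n_replicates,
      "replicates (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Ground-truth report for a synthetic dataset
#'
#' @param dataset A [generate_dataset()] result.
#' @return data.frame aligned with the chemical order: `chemical_id`,
#'   `log_ie`, `log_rf`, `top_linear_level`, `top_linear_conc`.
#' @export
truth_report <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dataset$truth
}

#' Write the synthetic input tables as delimited text
#'
#' Writes `chemicals.csv` (`chemical_id`, `name`, `formula`,
#' `retention_time_min`), `descriptors.csv` (chemical id + one column per
#' descriptor), `calibration.csv` (`chemical_id`, `concentration_nmol_L`,
#' `replicate`, `area`) and `truth.csv` into `dir`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chem <- dataset$chemicals
  names(chem)[names(chem) == "retention_time"] <- "retention_time_min"
  desc <- data.frame(chemical_id = rownames(dataset$descriptor_matrix),
                     dataset$descriptor_matrix, check.names = FALSE,
                     stringsAsFactors = FALSE)
  cal <- do.call(rbind, lapply(dataset$calibration, function(s) {
    nrep <- vapply(s$areas, length, 1L)
    data.frame(chemical_id = s$chemical_id,
               concentration_nmol_L = rep(s$concentrations * 1e9, nrep),
               replicate = unlist(lapply(nrep, seq_len)),
               area = unlist(s$areas),
               stringsAsFactors = FALSE)
  }))
  paths <- c(chemicals = file.path(dir, "chemicals.csv"),
             descriptors = file.path(dir, "descriptors.csv"),
             calibration = file.path(dir, "calibration.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(chem, paths["chemicals"], row.names = FALSE)
  utils::write.csv(desc, paths["descriptors"], row.names = FALSE)
  utils::write.csv(cal, paths["calibration"], row.names = FALSE)
  utils::write.csv(dataset$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
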