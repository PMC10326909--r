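#' Pipeline configuration
#'
#' Bundles input-table paths and stage parameters for [run_pipeline()].
#'
#' @param chemicals_file CSV of chemicals: `chemical_id`, `name`, `formula`,
#'   `retention_time_min`.
#' @param descriptors_file CSV of descriptors: `chemical_id` plus one
#'   numeric column per descriptor.
#' @param calibration_file CSV of calibration areas: `chemical_id`,
#'   `concentration_nmol_L`, `replicate`, `area`.
#' @param out_dir Run directory for all artifacts.
#' @param gradient A [gradient_program()] (used for the eluent report).
#' @param rel_residual_tol,replicate_rsd_tol Linear-range detection
#'   tolerances; see [detect_linear_range()].
#' @param freq_cut,cor_cutoff Descriptor filter thresholds; see
#'   [filter_descriptors()].
#' @param hyper An [rrf_hyperparams()]; `NULL` with a `tune_grid` enables
#'   tuning.
#' @param tune_grid Optional hyperparameter grid for
#'   [tune_hyperparameters()].
#' @param n_folds Cross-validation folds, default 10.
#' @param mc Optional list of Monte Carlo settings (`k_values`, `n_rep`)
#'   enabling the calibrant-selection study.
#' @param seed Global seed, mandatory for every stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(chemicals_file, descriptors_file,
                            calibration_file, out_dir,
                            gradient = default_gradient(),
                            rel_residual_tol = 0.2, replicate_rsd_tol = 0.3,
                            freq_cut = 19, cor_cutoff = 0.75,
                            hyper = NULL, tune_grid = NULL,
                            n_folds = 10, mc = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(chemicals_file = chemicals_file,
                 descriptors_file = descriptors_file,
                 calibration_file = calibration_file,
                 out_dir = out_dir, gradient = gradient,
                 rel_residual_tol = rel_residual_tol,
                 replicate_rsd_tol = replicate_rsd_tol,
                 freq_cut = freq_cut, cor_cutoff = cor_cutoff,
                 hyper = hyper, tune_grid = tune_grid,
                 n_folds = as.integer(n_folds), mc = mc,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.read_table <- function(path, required) {
  if (!file.exists(path)) stop("input table not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  tab
}

.check_numeric <- function(tab, cols, path) {
  for (cl in cols) {
    bad <- which(!is.finite(tab[[cl]]))
    if (length(bad) > 0L) {
      stop("file ", path, ", row ", bad[1L], ", column ", cl,
           ": non-numeric or missing value")
    }
  }
  invisible(tab)
}

# rolling polynomial checksum over the deparsed config, for the manifest
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the semiquantification pipeline end to end
#'
#' Stages: calibrate (isotope-corrected response factors with linear-range
#' detection) -> filter descriptors -> rank-stratified cross-validated
#' forest training (optionally tuned) -> robust transfer recalibration of
#' the out-of-fold predictions -> quantification of every chemical at its
#' linear-range levels -> error-factor summary -> optional Monte Carlo
#' calibrant-selection study. Every artifact is a CSV (or JSON summary) in
#' `config$out_dir`, and `manifest.json` records the config hash, seed and
#' package version; rerunning with the same config and seed reproduces all
#' numbers.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage-level progress and counts.
#' @return Invisibly, a list with the in-memory stage results: `rf_table`,
#'   `filtered` (descriptor_matrix), `folds`, `oof_pred`, `transfer`,
#'   `quant`, `summary`, `mc` (or `NULL`), `out_dir`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[sfcquant] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  chem <- .read_table(config$chemicals_file,
                      c("chemical_id", "formula", "retention_time_min"))
  .check_numeric(chem, "retention_time_min", config$chemicals_file)
  desc <- .read_table(config$descriptors_file, "chemical_id")
  cal <- .read_table(config$calibration_file,
                     c("chemical_id", "concentration_nmol_L", "replicate",
                       "area"))
  .check_numeric(cal, c("concentration_nmol_L", "area"),
                 config$calibration_file)

  # -- calibrate ------------------------------------------------------------
  series_list <- lapply(split(cal, cal$chemical_id), function(d) {
    conc <- sort(unique(d$concentration_nmol_L)) * 1e-9
    areas <- lapply(conc, function(cc) {
      d$area[abs(d$concentration_nmol_L * 1e-9 - cc) < 1e-15]
    })
    calibration_series(d$chemical_id[1L], conc, areas)
  })
  formulas <- stats::setNames(as.list(chem$formula), chem$chemical_id)
  estimates <- lapply(series_list, function(s) {
    estimate_response_factor(s, formula = formulas[[s$chemical_id]],
                             rel_residual_tol = config$rel_residual_tol,
                             replicate_rsd_tol = config$replicate_rsd_tol)
  })
  rf_table <- estimate_response_factors(
    series_list, formulas, rel_residual_tol = config$rel_residual_tol,
    replicate_rsd_tol = config$replicate_rsd_tol)
  utils::write.csv(rf_table, file.path(config$out_dir, "rf_table.csv"),
                   row.names = FALSE)
  ok_ids <- rf_table$chemical_id[rf_table$ok]
  say("calibrate: ", length(ok_ids), "/", nrow(rf_table),
      " chemicals with a valid linear range")

  # -- filter descriptors ---------------------------------------------------
  dm <- as.matrix(desc[, setdiff(names(desc), "chemical_id"), drop = FALSE])
  rownames(dm) <- desc$chemical_id
  dm <- dm[match(ok_ids, rownames(dm)), , drop = FALSE]
  if (anyNA(dm)) stop("descriptor table misses chemicals present in the calibration table")
  filtered <- filter_descriptors(dm, freq_cut = config$freq_cut,
                                 cor_cutoff = config$cor_cutoff)
  utils::write.csv(
    data.frame(descriptor = filtered$descriptor_names,
               kept = filtered$kept_mask,
               removal_reason = filtered$removal_reason),
    file.path(config$out_dir, "descriptor_filter_log.csv"),
    row.names = FALSE)
  say("filter: ", sum(filtered$kept_mask), "/", ncol(dm),
      " descriptors kept")

  # -- train / cross-validate ----------------------------------------------
  log_rf <- stats::setNames(rf_table$log10_rf[rf_table$ok], ok_ids)
  x <- filtered$kept
  hyper <- config$hyper
  if (is.null(hyper)) {
    if (is.null(config$tune_grid)) {
      hyper <- rrf_hyperparams(mtry = max(1L, floor(ncol(x) / 3)))
    } else {
      tuned <- tune_hyperparameters(x, log_rf, config$tune_grid,
                                    seed = config$seed + 77L)
      hyper <- tuned$best
      utils::write.csv(tuned$results,
                       file.path(config$out_dir, "tuning_results.csv"),
                       row.names = FALSE)
      say("tune: mtry = ", hyper$mtry, ", coef_reg = ", hyper$coef_reg,
          ", coef_imp = ", hyper$coef_imp)
    }
  }
  if (hyper$mtry > ncol(x)) {
    say("train: mtry reduced to the ", ncol(x), " descriptors that survived filtering")
    hyper$mtry <- ncol(x)
  }
  folds <- make_folds_rank_stratified(log_rf, k = config$n_folds,
                                      seed = config$seed)
  oof <- cross_validated_predictions(x, log_rf, hyper, folds,
                                     seed = config$seed + 100L)
  names(oof) <- ok_ids
  model <- train_rrf(x, log_rf, hyper, seed = config$seed + 200L)
  utils::write.csv(
    data.frame(chemical_id = ok_ids, fold = folds, log10_rf = log_rf,
               oof_pred_log10_rf = oof),
    file.path(config$out_dir, "oof_predictions.csv"), row.names = FALSE)
  imp <- sort(model$importances, decreasing = TRUE)
  utils::write.csv(data.frame(descriptor = names(imp), importance = imp),
                   file.path(config$out_dir, "importances.csv"),
                   row.names = FALSE)
  say("train: out-of-fold Spearman rho = ",
      round(stats::cor(oof, log_rf, method = "spearman"), 3))

  # -- transfer -------------------------------------------------------------
  line <- fit_transfer(oof, log_rf)
  say("transfer: slope = ", round(line$slope, 3), ", intercept = ",
      round(line$intercept, 3))

  # -- quantify -------------------------------------------------------------
  areas <- quant_input_table(series_list[ok_ids], estimates[ok_ids],
                             formulas)
  rf_pred <- stats::setNames(rf_from_ie(oof, line), ok_ids)
  quant <- quantify_chemicals(areas, rf_pred)
  utils::write.csv(quant, file.path(config$out_dir, "quant_results.csv"),
                   row.names = FALSE)
  smry <- summarize_errors(quant)
  say("quantify: median EF = ", round(smry$median_ef, 3), ", mean EF = ",
      round(smry$mean_ef, 3), ", ",
      round(100 * smry$frac_under_10, 1), "% under 10x")

  # -- optional Monte Carlo study ------------------------------------------
  mc_out <- NULL
  if (!is.null(config$mc)) {
    rt <- stats::setNames(chem$retention_time_min,
                          chem$chemical_id)[ok_ids]
    mc_samples <- run_mc_study(
      log_ie_pred = oof, log_rf_measured = log_rf, areas = areas,
      retention_time = rt,
      k_values = if (is.null(config$mc$k_values)) 5:20 else config$mc$k_values,
      n_rep = if (is.null(config$mc$n_rep)) 200 else config$mc$n_rep,
      seed = config$seed + 300L)
    mc_out <- list(samples = mc_samples, aggregates = aggregate_mc(mc_samples))
    utils::write.csv(mc_samples, file.path(config$out_dir, "mc_samples.csv"),
                     row.names = FALSE)
    utils::write.csv(mc_out$aggregates$by_k,
                     file.path(config$out_dir, "mc_by_k.csv"),
                     row.names = FALSE)
    say("mc-study: ", nrow(mc_samples), " samples")
  }

  manifest <- list(
    package = "sfcquant",
    version = as.character(utils::packageVersion("sfcquant")),
    seed = config$seed,
    config_hash = .config_hash(config),
    n_chemicals_in = nrow(rf_table),
    n_chemicals_calibrated = length(ok_ids),
    n_descriptors_kept = sum(filtered$kept_mask),
    summary = smry)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(rf_table = rf_table, filtered = filtered, folds = folds,
                 oof_pred = oof, hyper = hyper, model = model,
                 transfer = line, quant = quant, summary = smry,
                 mc = mc_out, out_dir = config$out_dir))
}

#' Build the quantification input table from calibration data
#'
#' One row per chemical and linear-range level, with the isotope-corrected
#' mean replicate area — the signal that [quantify_chemicals()] converts to
#' a concentration.
#'
#' @param series_list Named list of [calibration_series()].
#' @param estimates Named list of `rf_estimate` objects (for the linear
#'   levels), aligned with `series_list`.
#' @param formulas Named list/vector of molecular formulas.
#' @return data.frame: `chemical_id`, `concentration` (mol/L),
#'   `corrected_area`.
#' @export
quant_input_table <- function(series_list, estimates, formulas) {
  rows <- mapply(function(s, e) {
    lin <- e$linear_levels
    if (length(lin) < 3L || !e$ok) return(NULL)
    frac <- if (is.null(formulas[[s$chemical_id]])) 1 else
      monoisotopic_fraction(formulas[[s$chemical_id]])
    data.frame(chemical_id = s$chemical_id,
               concentration = s$concentrations[lin],
               corrected_area = vapply(s$areas[lin], function(a) {
                 correct_area(mean(a), frac)
               }, 0),
               stringsAsFactors = FALSE)
  }, series_list, estimates, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
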