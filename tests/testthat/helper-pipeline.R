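# full semiquantification chain on the default synthetic study conditions;
# shared by the accuracy and Monte Carlo acceptance checks
full_chain_run <- function(seed, n_trees = 300) {
  ds <- generate_dataset(synth_config(seed = seed))
  fm <- stats::setNames(as.list(ds$chemicals$formula),
                        ds$chemicals$chemical_id)
  est <- lapply(ds$calibration, function(s) {
    estimate_response_factor(s, fm[[s$chemical_id]])
  })
  rft <- estimate_response_factors(ds$calibration, fm)
  ok_ids <- rft$chemical_id[rft$ok]
  log_rf <- stats::setNames(rft$log10_rf[rft$ok], ok_ids)
  fil <- filter_descriptors(ds$descriptor_matrix[ok_ids, , drop = FALSE])
  hyper <- rrf_hyperparams(mtry = min(86L, ncol(fil$kept)), coef_reg = 1,
                           coef_imp = 0.5, n_trees = n_trees)
  folds <- make_folds_rank_stratified(log_rf, 10, seed = seed)
  oof <- stats::setNames(
    cross_validated_predictions(fil$kept, log_rf, hyper, folds,
                                seed = seed + 100L),
    ok_ids)
  truth_rf <- ds$truth$log_rf[match(ok_ids, ds$truth$chemical_id)]
  line <- fit_transfer(oof, log_rf)
  areas <- quant_input_table(ds$calibration[ok_ids], est[ok_ids], fm)
  quant <- quantify_chemicals(areas,
                              stats::setNames(rf_from_ie(oof, line), ok_ids))
  list(dataset = ds, ok_ids = ok_ids, log_rf = log_rf, oof = oof,
       truth_rf = truth_rf, areas = areas, quant = quant,
       summary = summarize_errors(quant),
       rt = stats::setNames(ds$chemicals$retention_time,
                            ds$chemicals$chemical_id)[ok_ids])
}
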