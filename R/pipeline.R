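# End-to-end pipeline over the synthetic study: simulate, harmonize, fit
# signatures, estimate and scale activity, phenotype and subgroup, variance
# attribution, pharmacology. Every stage's result is written as TSV so the
# run is fully inspectable; the command-line wrapper in inst/cli is a thin
# shell over this function.

#' Run the full GFRN analysis pipeline on synthetic study data
#'
#' Generates a synthetic training set, tumor cohort, protein matrix and
#' dose-response panel; harmonizes training batches and the cohort
#' (reference-batch adjustment, two rounds); fits the seven pathway
#' signatures; estimates and z-scales cohort activity; calls phenotypes and
#' k-means subgroups; runs the PCA variance attribution; and fits the drug
#' panel with subgroup drug tests. All stage outputs are written under
#' `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every random draw.
#' @param cfg Optional [synth_config()]; by default a moderate-size config
#'   built from `seed`.
#' @param K Signature size used for the fit (default 100).
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_gfrn_pipeline <- function(out_dir, seed = 1, cfg = NULL, K = 100) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(cfg)) cfg <- synth_config(seed = seed)
  pathf <- function(f) file.path(out_dir, f)

  train <- simulate_training(cfg)
  cohort <- simulate_cohort(cfg, train$truth)
  pd <- simulate_protein_drug(cfg, cohort$truth)
  write_expression_matrix(train$expr, pathf("training_expression.tsv"))
  utils::write.table(train$annotation, pathf("training_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_matrix(cohort$expr, pathf("cohort_expression.tsv"))
  utils::write.table(pd$dose_response, pathf("dose_response.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  train_adj <- reference_batch_adjust(
    train$expr, train$annotation$batch, reference_batch = 1,
    covariates = train$annotation$group)
  harm <- harmonize_train_test(train_adj, cohort$expr,
                               batch = rep(1, ncol(train_adj)),
                               reference_batch = 1)
  model <- gfrn_signatures(harm$train, train$annotation$group, K = K,
                           anchors = train$truth$anchors)
  for (p in model$pathways) {
    write_signature(model$signatures[[p]],
                    pathf(paste0("signature_", p, ".tsv")))
  }

  act <- predict(model, harm$test)
  scaled <- scale_activities(act)
  calls <- call_phenotype(scaled)
  km <- kmeans_subgroups(scaled, seed = seed + 10L)
  calls <- label_subgroups(km$cluster, calls, scaled)
  write_supplementary_activity(scaled, calls,
                               pathf("activity_phenotypes.tsv"))

  pcs <- pca_samples(cohort$expr)
  pc_act <- correlate_pcs_with_activity(pcs, act)
  cmp <- nested_model_comparison(
    pcs$scores[calls$sample, 2], base = calls$phenotype,
    added = calls$subgroup)
  utils::write.table(
    data.frame(pc = rownames(pc_act$rho), pc_act$rho, check.names = FALSE),
    pathf("pc_activity_correlation.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  fits <- fit_dose_response_panel(pd$dose_response)
  utils::write.table(fits, pathf("dose_response_fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  subgroups <- stats::setNames(calls$subgroup, calls$sample)
  tests <- subgroup_drug_tests(
    fits, subgroups,
    comparisons = list(c("survival_HER2_high", "survival_HER2_low"),
                       c("growth_BAD_high", "growth_BAD_low")))
  utils::write.table(tests, pathf("subgroup_drug_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  corr <- activity_drug_correlation(act, fits)
  utils::write.table(
    data.frame(pathway = rownames(corr$rho), corr$rho, check.names = FALSE),
    pathf("activity_drug_correlation.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  calls_bin <- binarize_sensitivity(fits)
  utils::write.table(calls_bin, pathf("sensitivity_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(cfg = cfg, train = train, cohort = cohort, pd = pd,
                 model = model, activity = act, scaled = scaled,
                 calls = calls, kmeans = km, pca = pcs,
                 pc_activity = pc_act, model_comparison = cmp,
                 fits = fits, drug_tests = tests, drug_correlation = corr))
}
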