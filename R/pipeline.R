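#' Run the full screening pipeline on a cohort
#'
#' End-to-end orchestration of the method: stratified train/test split,
#' per-probe age/sex-adjusted reference fitted to the training controls,
#' z-scoring of all samples, leakage-free feature engineering (z-filter,
#' target-probe features, UMAP global features, correlation pruning),
#' bagged weighted-ensemble training, test-set prediction, and evaluation.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param samples Sample sheet tibble; if no split is assigned,
#'   [split_train_test()] is applied under `config$seed`.
#' @param regions Named list of target-region probe-id vectors.
#' @param config An `"ms_config"`.
#' @param k Spline basis dimension for the reference fit.
#' @return List with class `"ms_pipeline"`: `samples`, `reference`,
#'   `panel`, `features`, `ensemble`, `predictions`, `evaluation`.
#' @export
run_pipeline <- function(beta, samples, regions, config = pipeline_config(),
                         k = 8L) {
  stopifnot(is.matrix(beta))
  .check_regions(regions, rownames(beta))
  if (all(samples$split == "unassigned")) {
    samples <- split_train_test(samples, config$train_fraction, config$seed)
  }
  reference <- fit_reference(beta, samples, k = k)
  panel <- score_cohort(beta, samples, reference, lambda = config$lambda)
  features <- build_features(panel, samples, regions, config)

  train_ids <- rownames(features$train)
  y_train <- samples$class_label[match(train_ids, samples$sample_id)]
  ensemble <- train_ensemble(features$train, y_train, k = config$bag_folds,
                             class_order = config$class_levels,
                             seed = config$seed)

  predictions <- NULL; evaluation <- NULL
  if (!is.null(features$test) && nrow(features$test)) {
    predictions <- predict(ensemble, features$test)
    predictions$true <- samples$class_label[match(predictions$sample_id,
                                                  samples$sample_id)]
    evaluation <- evaluate_predictions(predictions$true,
                                       predictions$predicted,
                                       config$class_levels)
  }
  structure(
    list(samples = samples, reference = reference, panel = panel,
         features = features, ensemble = ensemble,
         predictions = predictions, evaluation = evaluation,
         config = config),
    class = "ms_pipeline"
  )
}
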