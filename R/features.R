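#' Stratified train/test split
#'
#' Assigns `round(fraction * class size)` samples of every class to the
#' train split and the remainder to test, sampling within class under the
#' seed. Classes of size 1 are rejected (they cannot appear in both
#' splits).
#'
#' @param samples Sample sheet tibble.
#' @param fraction Train fraction in (0,1).
#' @param seed Integer seed.
#' @return `samples` with the `split` column filled (`"train"`/`"test"`).
#' @export
split_train_test <- function(samples, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  sizes <- table(samples$class_label)
  if (any(sizes < 2L)) {
    abort(paste0("Every class needs >= 2 samples to split; too small: ",
                 paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  samples$split <- "test"
  for (cl in sort(unique(samples$class_label))) {
    idx <- which(samples$class_label == cl)
    n_train <- round(fraction * length(idx))
    n_train <- min(max(n_train, 1L), length(idx) - 1L)
    samples$split[sample(idx, n_train)] <- "train"
  }
  samples
}

#' Filter probes by z-score evidence in the training set
#'
#' Keeps probes that are significantly differentially methylated in at
#' least `min_samples` training samples (`|z| >= threshold` under the
#' chosen variant). Removes the bulk of never-outlying probes before
#' feature construction.
#'
#' @param panel An `"ms_zpanel"`.
#' @param train_ids Sample ids of the training split (default: all).
#' @param threshold Absolute z threshold (default 3).
#' @param min_samples Minimum flagged training samples (default 1).
#' @param variant Z-score variant (default `"adjusted"`).
#' @return Character vector of passing probe ids (panel order).
#' @export
filter_probes_by_z <- function(panel, train_ids = NULL, threshold = 3,
                               min_samples = 1L, variant = "adjusted") {
  stopifnot(threshold > 0, min_samples >= 1L)
  col <- .variant_col(variant)
  sub <- if (is.null(train_ids)) panel else panel[panel$sample_id %in% train_ids, ]
  counts <- tapply(abs(sub[[col]]) >= threshold, sub$probe_id, sum)
  probes <- unique(panel$probe_id)
  probes[probes %in% names(counts)[counts >= min_samples]]
}

#' Target-probe feature columns
#'
#' One feature per unique region probe that passed the z-filter, valued by
#' its adjusted z-score. Probes shared between regions are de-duplicated
#' preserving first occurrence.
#'
#' @param panel An `"ms_zpanel"`.
#' @param regions Named list of probe-id vectors.
#' @param passing_ids Probe ids surviving [filter_probes_by_z()].
#' @param variant Z-score variant used as the feature value.
#' @return Samples-by-probes numeric matrix.
#' @export
extract_target_features <- function(panel, regions, passing_ids,
                                    variant = "adjusted") {
  if (!length(regions)) abort("Empty region set.")
  target <- unique(unlist(regions, use.names = FALSE))
  keep <- target[target %in% passing_ids]
  if (!length(keep)) abort("No target-region probe passed the z-filter.")
  z <- panel_matrix(panel, variant)
  t(z[keep, , drop = FALSE])
}

#' UMAP global features
#'
#' Fits a UMAP embedding on the training samples' z-scores over the
#' passing non-target probes and projects test samples through the fitted
#' transform; the embedding summarises genome-wide methylation deviation
#' patterns outside the target loci into `n_dims` coordinates.
#'
#' @param z Samples-by-probes matrix of z-scores over passing non-target
#'   probes (training samples only).
#' @param n_dims Embedding dimensionality (default 50).
#' @param seed Integer seed (embeddings are seed-sensitive).
#' @param n_neighbors,min_dist UMAP hyperparameters (library defaults
#'   15 / 0.1).
#' @return List: `embedding` (train samples x `n_dims`, columns
#'   `umap_1..`), `model` (the fitted transform).
#' @export
umap_global_features <- function(z, n_dims = 50L, seed = 1L,
                                 n_neighbors = 15L, min_dist = 0.1) {
  stopifnot(is.matrix(z))
  if (nrow(z) < n_dims + 2L) {
    abort(sprintf("Need >= %d training samples for %d UMAP dims; reduce n_dims.",
                  n_dims + 2L, n_dims))
  }
  n_neighbors <- min(n_neighbors, nrow(z) - 1L)
  model <- uwot::umap(z, n_components = n_dims, n_neighbors = n_neighbors,
                      min_dist = min_dist, metric = "euclidean",
                      init = if (n_dims > 2L) "pca" else "spectral",
                      init_sdev = 1,
                      ret_model = TRUE, n_threads = 1L, n_sgd_threads = 0L,
                      seed = seed, verbose = FALSE)
  emb <- model$embedding
  dimnames(emb) <- list(rownames(z), paste0("umap_", seq_len(n_dims)))
  list(embedding = emb, model = model)
}

#' Project new samples through a fitted UMAP transform
#'
#' @param z New samples-by-probes matrix (same probe columns as the fit).
#' @param fit Result of [umap_global_features()].
#' @return New samples x dims matrix with `umap_*` column names.
#' @export
umap_project <- function(z, fit) {
  out <- uwot::umap_transform(z, fit$model, n_threads = 1L)
  dimnames(out) <- list(rownames(z), colnames(fit$embedding))
  out
}

#' Prune highly correlated features
#'
#' Stepwise mean-absolute-correlation heuristic: while any off-diagonal
#' absolute Pearson correlation among surviving features exceeds `cutoff`,
#' take the most correlated pair and drop the member with the larger mean
#' absolute correlation against all remaining features (ties drop the
#' later column). Zero-variance features are removed first with a warning
#' (their correlation is undefined).
#'
#' @param features Samples-by-features numeric matrix (training split).
#' @param cutoff Absolute correlation cutoff in (0,1\].
#' @return Character vector of retained feature names, in original order.
#' @export
prune_correlated <- function(features, cutoff = 0.9) {
  stopifnot(is.matrix(features), cutoff > 0, cutoff <= 1)
  nm <- colnames(features)
  const <- apply(features, 2L, function(v) isTRUE(all.equal(var(v), 0)) || var(v) == 0)
  if (any(const)) {
    warn(paste0("Removing zero-variance feature(s): ",
                paste(nm[const], collapse = ", ")))
    features <- features[, !const, drop = FALSE]
    nm <- nm[!const]
  }
  keep <- rep(TRUE, length(nm))
  cm <- abs(cor(features))
  diag(cm) <- 0
  repeat {
    sub <- cm[keep, keep, drop = FALSE]
    if (!length(sub) || max(sub) <= cutoff) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    pair <- rownames(sub)[ij]
    mac <- rowMeans(cm[pair, keep, drop = FALSE])
    drop_nm <- if (mac[1L] > mac[2L]) pair[1L]
      else if (mac[2L] > mac[1L]) pair[2L]
      else pair[which.max(match(pair, nm))]  # tie: later column
    keep[match(drop_nm, nm)] <- FALSE
  }
  nm[keep]
}

#' Assemble the classifier feature matrix
#'
#' Column-concatenates the target-probe and UMAP feature blocks (probe ids
#' and `umap_*` names must not collide) and restricts to the retained
#' feature names in their original order.
#'
#' @param target_features Samples x target-probes matrix.
#' @param umap_features Samples x dims matrix.
#' @param retained Feature names to keep (default: all).
#' @return Samples-by-features matrix.
#' @export
assemble_features <- function(target_features, umap_features, retained = NULL) {
  stopifnot(identical(rownames(target_features), rownames(umap_features)))
  if (length(intersect(colnames(target_features), colnames(umap_features)))) {
    abort("Feature name collision between target probes and UMAP dims.")
  }
  out <- cbind(target_features, umap_features)
  if (!is.null(retained)) {
    missing <- setdiff(retained, colnames(out))
    if (length(missing)) abort(paste0("Unknown retained feature(s): ",
                                      paste(missing, collapse = ", ")))
    out <- out[, colnames(out)[colnames(out) %in% retained], drop = FALSE]
  }
  out
}

#' Build train/test feature matrices without leakage
#'
#' Runs the full feature-engineering chain with every fitted component —
#' z-filter, UMAP embedding, correlation pruning — computed on the
#' training split only and applied to the test split as a separate step.
#'
#' @param panel An `"ms_zpanel"` covering all samples.
#' @param samples Sample sheet with `split` assigned.
#' @param regions Named list of target-region probe-id vectors.
#' @param config An `"ms_config"` (thresholds, UMAP dims, cutoff, seed).
#' @return List with class `"ms_features"`: `train`, `test` (matrices),
#'   `state` (passing/target probe ids, the UMAP fit, retained names).
#' @export
build_features <- function(panel, samples, regions,
                           config = pipeline_config()) {
  train_ids <- samples$sample_id[samples$split == "train"]
  test_ids <- samples$sample_id[samples$split == "test"]
  if (!length(train_ids)) abort("No training samples assigned.")

  passing <- filter_probes_by_z(panel, train_ids,
                                threshold = config$z_outlier_threshold,
                                min_samples = 1L)
  target <- unique(unlist(regions, use.names = FALSE))
  target_keep <- target[target %in% passing]
  if (!length(target_keep)) abort("No target-region probe passed the z-filter.")

  z_all <- t(panel_matrix(panel, "adjusted"))  # samples x probes
  global_probes <- setdiff(passing, target)
  if (length(global_probes) < 2L) abort("Too few non-target probes for global features.")

  umap_fit <- umap_global_features(z_all[train_ids, global_probes, drop = FALSE],
                                   n_dims = config$umap_dims,
                                   seed = config$seed)
  tgt_train <- z_all[train_ids, target_keep, drop = FALSE]
  pre_prune <- assemble_features(tgt_train, umap_fit$embedding)
  retained <- prune_correlated(pre_prune, config$correlation_cutoff)
  train <- pre_prune[, retained, drop = FALSE]

  test <- NULL
  if (length(test_ids)) {
    tgt_test <- z_all[test_ids, target_keep, drop = FALSE]
    umap_test <- umap_project(z_all[test_ids, global_probes, drop = FALSE],
                              umap_fit)
    test <- assemble_features(tgt_test, umap_test, retained)
  }
  structure(
    list(train = train, test = test,
         state = list(passing_probe_ids = passing,
                      target_probe_ids = target_keep,
                      global_probe_ids = global_probes,
                      umap_fit = umap_fit,
                      retained = retained,
                      n_pre_prune = ncol(pre_prune),
                      config = config)),
    class = "ms_features"
  )
}
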