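#' Pipeline configuration
#'
#' Collects the tunable constants used across the pipeline with their
#' defaults: the outlier threshold on z-scores, the alpha level for
#' p-value based flagging, the regularization weight pulling the per-probe
#' reference toward the cohort-global mean/SD, the UMAP embedding
#' dimensionality, the correlation-pruning cutoff, the train fraction,
#' the number of bagging folds, and the boundary-clipping epsilon applied
#' before the logit transform.
#'
#' @param seed Integer seed used by every stochastic stage.
#' @param z_outlier_threshold Absolute z-score at or above which a probe is
#'   called an outlier (default 3).
#' @param alpha Two-sided significance level for p-value flagging.
#' @param lambda Regularization weight in \[0,1\]; 1 = fully adjusted
#'   reference, 0 = fully global.
#' @param umap_dims Number of UMAP global-feature dimensions.
#' @param correlation_cutoff Absolute pairwise correlation above which one
#'   of a feature pair is pruned.
#' @param train_fraction Fraction of each class assigned to the train split.
#' @param bag_folds Number of cross-validation folds for bagged training.
#' @param logit_epsilon Beta-value clipping epsilon.
#' @param class_levels Recognised class labels (first must be the control
#'   label); extensible for synthetic experiments.
#' @return A list with class `"ms_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            z_outlier_threshold = 3,
                            alpha = 0.05,
                            lambda = 0.5,
                            umap_dims = 50L,
                            correlation_cutoff = 0.9,
                            train_fraction = 0.8,
                            bag_folds = 5L,
                            logit_epsilon = 1e-6,
                            class_levels = ms_class_levels) {
  stopifnot(
    z_outlier_threshold > 0,
    alpha > 0, alpha < 1,
    lambda >= 0, lambda <= 1,
    umap_dims >= 1,
    correlation_cutoff > 0, correlation_cutoff <= 1,
    train_fraction > 0, train_fraction < 1,
    bag_folds >= 2,
    logit_epsilon > 0, logit_epsilon < 0.5
  )
  structure(
    list(
      seed = as.integer(seed),
      z_outlier_threshold = z_outlier_threshold,
      alpha = alpha,
      lambda = lambda,
      umap_dims = as.integer(umap_dims),
      correlation_cutoff = correlation_cutoff,
      train_fraction = train_fraction,
      bag_folds = as.integer(bag_folds),
      logit_epsilon = logit_epsilon,
      class_levels = class_levels
    ),
    class = "ms_config"
  )
}

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a methylation beta matrix
#'
#' Reads a TSV/CSV with a `probe_id` first column and one numeric column per
#' sample, and returns a probes-by-samples numeric matrix. Values are
#' validated to lie in \[0,1\] and clipped into `[epsilon, 1 - epsilon]` so
#' the logit transform is defined downstream.
#'
#' @param path File path (`.csv` is comma-separated, anything else tab).
#' @param epsilon Boundary clipping epsilon.
#' @return Numeric matrix, rownames = probe ids, colnames = sample ids.
#' @export
read_beta_matrix <- function(path, epsilon = 1e-6) {
  delim <- .delim_for(path)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  if (ncol(df) < 2L) abort("Beta matrix needs a probe-id column plus at least one sample column.")
  probe_ids <- df[[1L]]
  if (anyDuplicated(probe_ids)) {
    abort(paste0("Duplicated probe id(s): ",
                 paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", ")))
  }
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
                 dimnames = list(probe_ids, names(df)[-1L]))
  for (j in seq_len(ncol(df) - 1L)) {
    col <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(col) & !is.na(df[[j + 1L]]) | is.na(df[[j + 1L]]))
    if (length(bad)) {
      abort(sprintf("Non-numeric or missing beta value at row %d (probe '%s'), column '%s'.",
                    bad[1L], probe_ids[bad[1L]], names(df)[j + 1L]))
    }
    vals[, j] <- col
  }
  if (any(vals < 0) || any(vals > 1)) {
    idx <- which(vals < 0 | vals > 1, arr.ind = TRUE)[1L, ]
    abort(sprintf("Beta value outside [0,1] at probe '%s', sample '%s'.",
                  rownames(vals)[idx[1L]], colnames(vals)[idx[2L]]))
  }
  clip_beta(vals, epsilon)
}

#' Write a beta matrix
#'
#' @param beta Probes-by-samples numeric matrix with dimnames.
#' @param path Output path (`.csv` comma-separated, else tab).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  df <- as_tibble(beta, rownames = "probe_id")
  readr::write_delim(df, path, delim = .delim_for(path), progress = FALSE)
  invisible(path)
}

.check_sample_sheet <- function(df, class_levels) {
  if (anyDuplicated(df$sample_id)) abort("Duplicate sample_id in sample sheet.")
  if (any(df$age_days < 0)) abort("Negative age in sample sheet.")
  bad_sex <- setdiff(unique(df$sex), ms_sex_levels)
  if (length(bad_sex)) abort(paste0("sex must be one of M/F; got: ", paste(bad_sex, collapse = ", ")))
  bad_cls <- setdiff(unique(df$class_label), class_levels)
  if (length(bad_cls)) abort(paste0("Unknown class label(s): ", paste(bad_cls, collapse = ", ")))
  invisible(df)
}

#' Read a sample sheet
#'
#' Expects CSV columns `sample_id`, `age_days` (or `age_years`, converted as
#' `round(years * 365.25)`), `sex` (`M`/`F`), `class_label`, and optionally
#' `split` (`train`/`test`/`unassigned`). Ages are normalised to integer
#' days (the canonical internal unit, fine enough to represent "1 day old").
#'
#' @param path CSV file path.
#' @param class_levels Accepted class labels.
#' @return A tibble with columns `sample_id`, `age_days`, `sex`,
#'   `class_label`, `split`.
#' @export
read_sample_sheet <- function(path, class_levels = ms_class_levels) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need_any <- c("age_days", "age_years")
  if (!all(c("sample_id", "sex", "class_label") %in% names(df)) ||
      !any(need_any %in% names(df))) {
    abort("Sample sheet needs columns sample_id, age_days (or age_years), sex, class_label.")
  }
  age_days <- if ("age_days" %in% names(df)) {
    as.numeric(df$age_days)
  } else {
    round(as.numeric(df$age_years) * DAYS_PER_YEAR)
  }
  if (any(is.na(age_days))) abort("Non-numeric age in sample sheet.")
  out <- tibble(
    sample_id = df$sample_id,
    age_days = as.integer(round(age_days)),
    sex = df$sex,
    class_label = df$class_label,
    split = if ("split" %in% names(df)) df$split else "unassigned"
  )
  bad_split <- setdiff(unique(out$split), c("train", "test", "unassigned"))
  if (length(bad_split)) abort(paste0("Unknown split value(s): ", paste(bad_split, collapse = ", ")))
  .check_sample_sheet(out, class_levels)
  out
}

#' Write a sample sheet
#'
#' @param samples Sample tibble as returned by [read_sample_sheet()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read a region-to-probe map
#'
#' Two-column TSV (`region_name`, `probe_id`). Probe order within each
#' region follows file order; the same probe may appear under several
#' regions (disorder loci can share probes).
#'
#' @param path TSV file path.
#' @return Named list of character vectors of probe ids.
#' @export
read_region_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0L) abort("Region map is empty.")
  if (ncol(df) < 2L) abort("Region map must have two columns: region_name, probe_id.")
  split(df[[2L]], factor(df[[1L]], levels = unique(df[[1L]])))
}

#' Write a region-to-probe map
#'
#' @param regions Named list of probe-id character vectors.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_map <- function(regions, path) {
  stopifnot(is.list(regions), !is.null(names(regions)), all(lengths(regions) > 0L))
  df <- tibble(
    region_name = rep(names(regions), lengths(regions)),
    probe_id = unlist(regions, use.names = FALSE)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# Probe ids referenced by a region set must exist in the beta matrix.
.check_regions <- function(regions, probe_ids) {
  missing <- setdiff(unlist(regions, use.names = FALSE), probe_ids)
  if (length(missing)) {
    abort(paste0("Region probes absent from beta matrix: ",
                 paste(head(missing, 5L), collapse = ", "),
                 if (length(missing) > 5L) " ..."))
  }
  invisible(regions)
}
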