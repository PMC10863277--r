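#' Outlier z-scores for logit-transformed beta values
#'
#' Three variants of the same standardization of a logit-scale methylation
#' value `x`:
#' * `z_unadjusted()` — against the cohort-global mean and SD,
#'   `(x - globalMu) / globalSigma`;
#' * `z_adjusted()` — against the age/sex-specific reference,
#'   `(x - mu) / sigma`;
#' * `z_regularized()` — against the adjusted reference shrunk toward the
#'   global one: `mu_reg = lambda * mu + (1 - lambda) * globalMu`,
#'   `sigma_reg = lambda * sigma + (1 - lambda) * globalSigma`. At
#'   `lambda = 1` this is exactly the adjusted score, at `lambda = 0`
#'   exactly the unadjusted one; intermediate weights trade power for
#'   type-I error control at modest cohort sizes.
#'
#' @param x_logit Logit-scale value(s).
#' @param global List with `globalMu`, `globalSigma` (see
#'   [compute_global_stats()]).
#' @param mu,sigma Age/sex-specific reference mean and SD (`sigma > 0`).
#' @param lambda Regularization weight in \[0,1\].
#' @return Numeric z-score(s).
#' @export
z_unadjusted <- function(x_logit, global) {
  if (!is.finite(global$globalSigma) || global$globalSigma <= 0) {
    abort("Degenerate global stats (sigma <= 0); probe refused.")
  }
  (x_logit - global$globalMu) / global$globalSigma
}

#' @rdname z_unadjusted
#' @export
z_adjusted <- function(x_logit, mu, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) abort("sigma must be > 0.")
  (x_logit - mu) / sigma
}

#' @rdname z_unadjusted
#' @export
z_regularized <- function(x_logit, mu, sigma, global, lambda = 0.5) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) abort("sigma must be > 0.")
  if (!is.finite(global$globalSigma) || global$globalSigma <= 0) {
    abort("Degenerate global stats (sigma <= 0); probe refused.")
  }
  mu_reg <- lambda * mu + (1 - lambda) * global$globalMu
  sigma_reg <- lambda * sigma + (1 - lambda) * global$globalSigma
  (x_logit - mu_reg) / sigma_reg
}

#' Two-sided normal p-value for a z-score
#'
#' @param z Finite z-score(s).
#' @return `2 * (1 - pnorm(|z|))`, in (0, 1\].
#' @export
p_two_sided <- function(z) 2 * pnorm(-abs(z))

#' Call a z-score an outlier
#'
#' Inclusive threshold rule: `|z| >= threshold`.
#'
#' @param z Z-score(s).
#' @param threshold Positive threshold (default 3).
#' @return Logical vector.
#' @export
call_outlier <- function(z, threshold = 3) {
  stopifnot(threshold > 0)
  abs(z) >= threshold
}

#' Score a cohort against a fitted reference
#'
#' Computes, for every probe and sample, the three z-score variants and
#' their two-sided normal p-values. Probes with degenerate global stats
#' (all-identical control values) are refused: dropped with a warning.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param samples Sample sheet tibble.
#' @param reference An `"ms_reference"` from [fit_reference()].
#' @param lambda Regularization weight.
#' @return Long tibble with class `"ms_zpanel"`: `probe_id`, `sample_id`,
#'   `z_unadj`, `z_adj`, `z_reg`, `p_unadj`, `p_adj`, `p_reg`.
#' @export
score_cohort <- function(beta, samples, reference, lambda = 0.5) {
  stopifnot(inherits(reference, "ms_reference"), is.matrix(beta))
  keep <- intersect(rownames(beta), reference$global$probe_id)
  if (!length(keep)) abort("No probes shared between beta matrix and reference.")
  glob <- reference$global[match(keep, reference$global$probe_id), ]
  if (any(glob$degenerate)) {
    warn(sprintf("Refusing %d probe(s) with degenerate global stats.",
                 sum(glob$degenerate)))
    keep <- keep[!glob$degenerate]
    glob <- glob[!glob$degenerate, ]
  }
  samples <- samples[match(colnames(beta), samples$sample_id), ]
  x <- logit(beta[keep, , drop = FALSE])

  gi <- .grid_index(reference$grid, samples$age_days)
  mu <- matrix(NA_real_, length(keep), ncol(x))
  sg <- mu
  for (sx in ms_sex_levels) {
    cols <- which(samples$sex == sx)
    if (!length(cols)) next
    mu[, cols] <- reference$mu[[sx]][keep, gi[cols], drop = FALSE]
    sg[, cols] <- reference$sigma[[sx]][keep, gi[cols], drop = FALSE]
  }

  z_un <- (x - glob$globalMu) / glob$globalSigma
  z_ad <- (x - mu) / sg
  mu_r <- lambda * mu + (1 - lambda) * glob$globalMu
  sg_r <- lambda * sg + (1 - lambda) * glob$globalSigma
  z_re <- (x - mu_r) / sg_r

  out <- tibble(
    probe_id = rep(keep, times = ncol(x)),
    sample_id = rep(colnames(x), each = length(keep)),
    z_unadj = as.vector(z_un),
    z_adj = as.vector(z_ad),
    z_reg = as.vector(z_re),
    p_unadj = p_two_sided(as.vector(z_un)),
    p_adj = p_two_sided(as.vector(z_ad)),
    p_reg = p_two_sided(as.vector(z_re))
  )
  class(out) <- c("ms_zpanel", class(out))
  out
}

.variant_col <- function(variant) {
  switch(match.arg(variant, ms_methods),
         unadjusted = "z_unadj", adjusted = "z_adj", regularized = "z_reg")
}

#' Extract a probes-by-samples matrix from a z-score panel
#'
#' @param panel An `"ms_zpanel"` tibble from [score_cohort()].
#' @param variant `"unadjusted"`, `"adjusted"` or `"regularized"`.
#' @return Numeric matrix, probes in rows, samples in columns.
#' @export
panel_matrix <- function(panel, variant = "adjusted") {
  col <- .variant_col(variant)
  probes <- unique(panel$probe_id)
  ids <- unique(panel$sample_id)
  matrix(panel[[col]], nrow = length(probes), ncol = length(ids),
         dimnames = list(probes, ids))
}

#' Per-sample count of outlier probes in a region
#'
#' For each sample, counts how many of the region's probes have
#' `|z| >= threshold` under the chosen variant — the probe-sensitivity
#' summary used to compare detection before and after age/sex adjustment.
#'
#' @param panel An `"ms_zpanel"`.
#' @param region_probes Character vector of probe ids (non-empty, all
#'   present in the panel).
#' @param sample_ids Samples to summarise (default: all in the panel).
#' @param variant Z-score variant.
#' @param threshold Outlier threshold.
#' @return Tibble: `sample_id`, `outlier_count`, `n_region_probes`.
#' @export
region_sensitivity <- function(panel, region_probes, sample_ids = NULL,
                               variant = "adjusted", threshold = 3) {
  if (!length(region_probes)) abort("Empty region.")
  missing <- setdiff(region_probes, unique(panel$probe_id))
  if (length(missing)) {
    abort(paste0("Region probes absent from panel: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  col <- .variant_col(variant)
  sub <- panel[panel$probe_id %in% region_probes, ]
  if (!is.null(sample_ids)) sub <- sub[sub$sample_id %in% sample_ids, ]
  sub |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      outlier_count = sum(call_outlier(.data[[col]], threshold)),
      n_region_probes = length(region_probes),
      .groups = "drop"
    )
}
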