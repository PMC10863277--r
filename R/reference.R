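#' Discretized reference age grid
#'
#' The per-probe model is evaluated on a fixed age grid rather than stored
#' as a fitted object: one-day steps through the first year (days 0-365),
#' monthly steps through the second year (months 13-24 at 30.4375
#' days/month), then yearly steps from age 3 to 85 (365.25 days/year),
#' all rounded to integer days and de-duplicated. The grid is densest in
#' infancy, where methylation changes fastest.
#'
#' @return Strictly increasing integer vector of grid ages in days
#'   (461 entries, 0 to 31046).
#' @export
build_age_grid <- function() {
  days <- 0:365
  months <- round(13:24 * DAYS_PER_MONTH)
  years <- round(3:85 * DAYS_PER_YEAR)
  sort(unique(as.integer(c(days, months, years))))
}

#' Global (cohort-wide) location and scale for one probe
#'
#' Sample mean and SD (denominator n-1) of the logit-transformed control
#' betas. A probe whose values are all identical has zero SD and is flagged
#' degenerate; scoring refuses such probes.
#'
#' @param logit_values Numeric vector of logit betas (length >= 2).
#' @return List with `globalMu`, `globalSigma`, `degenerate`.
#' @export
compute_global_stats <- function(logit_values) {
  if (length(logit_values) < 2L) abort("Need at least 2 values for global stats.")
  s <- sd(logit_values)
  list(globalMu = mean(logit_values), globalSigma = s,
       degenerate = !is.finite(s) || s <= 0)
}

# Minimum controls for an age/sex fit; below this (or with one sex absent,
# or on fitter failure) the model falls back to the constant global model,
# degrading gracefully to the unadjusted method.
MIN_FIT_N <- 10L

# Fit the location-scale model for one probe and return a predictor
# closure over (age_days, sex). mu = s(log(1+age_years)) + b*[sex==M],
# log-scale linear predictor likewise; penalized regression splines with
# REML smoothing selection. Returns NULL on failure.
.fit_locscale <- function(y, age_days, sex, k = 8L) {
  d <- data.frame(y = y, aget = log1p(age_days / DAYS_PER_YEAR),
                  sexM = factor(as.integer(sex == "M"), levels = c(0L, 1L)))
  k <- min(k, max(4L, floor(length(y) / 5)))
  fit <- tryCatch(
    suppressWarnings(
      mgcv::gam(list(y ~ s(aget, k = k, bs = "cr") + sexM,
                     ~ s(aget, k = k, bs = "cr") + sexM),
                family = mgcv::gaulss(), data = d, optimizer = "efs")
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  function(age_days, sex) {
    nd <- data.frame(aget = log1p(age_days / DAYS_PER_YEAR),
                     sexM = factor(as.integer(sex == "M"), levels = c(0L, 1L)))
    pr <- predict(fit, nd, type = "response")
    # gaulss response columns: mu and 1/sigma
    list(mu = as.numeric(pr[, 1L]),
         sigma = pmax(1 / as.numeric(pr[, 2L]), 1e-4))
  }
}

#' Fit the age/sex-adjusted reference model for one probe
#'
#' Fits a Gaussian location-scale model to the logit-transformed control
#' betas — mean and log-scale each modeled as a penalized spline in
#' `log(1 + age_years)` plus an additive sex shift — and discretizes the
#' fit onto the reference [build_age_grid()] for both sexes. With fewer
#' than 10 controls, a single represented sex, or a fitter failure, the
#' model falls back to the constant global mean/SD (`converged = FALSE`).
#'
#' @param logit_values Logit-scale control values.
#' @param age_days Integer ages in days.
#' @param sex `"M"`/`"F"` per control.
#' @param grid Age grid in days (default [build_age_grid()]).
#' @param k Spline basis dimension (default 8, reduced for small n).
#' @return List with class `"ms_probe_ref"`: `grid`, `mu`/`sigma` (matrices
#'   grid x sex with columns `F`, `M`), `global`, `n_controls`, `converged`.
#' @export
fit_probe_model <- function(logit_values, age_days, sex,
                            grid = build_age_grid(), k = 8L) {
  stopifnot(length(logit_values) == length(age_days),
            length(logit_values) == length(sex))
  global <- compute_global_stats(logit_values)
  pred <- NULL
  if (length(logit_values) >= MIN_FIT_N && length(unique(sex)) == 2L &&
      !global$degenerate) {
    pred <- .fit_locscale(logit_values, age_days, sex, k = k)
  }
  ng <- length(grid)
  if (is.null(pred)) {
    mu <- matrix(global$globalMu, ng, 2L, dimnames = list(NULL, ms_sex_levels))
    sigma <- matrix(max(global$globalSigma, 1e-4), ng, 2L,
                    dimnames = list(NULL, ms_sex_levels))
    converged <- FALSE
  } else {
    pF <- pred(grid, rep("F", ng)); pM <- pred(grid, rep("M", ng))
    mu <- cbind(F = pF$mu, M = pM$mu)
    sigma <- cbind(F = pF$sigma, M = pM$sigma)
    converged <- TRUE
  }
  structure(
    list(grid = grid, mu = mu, sigma = sigma, global = global,
         n_controls = length(logit_values), converged = converged),
    class = "ms_probe_ref"
  )
}

# Index of the nearest grid age; ties break to the younger grid age
# (which.min returns the first minimum on a sorted grid).
.grid_index <- function(grid, age_days) {
  vapply(age_days, function(a) which.min(abs(grid - a)), integer(1L))
}

#' Look up the reference mean and SD for a sample
#'
#' Returns the grid entry at the age nearest (in days) to the sample's age
#' — ties break to the younger grid age — for the sample's sex.
#'
#' @param model An `"ms_probe_ref"` from [fit_probe_model()].
#' @param age_days Ages in days.
#' @param sex `"M"`/`"F"` per sample.
#' @return Tibble with columns `mu`, `sigma`.
#' @export
lookup <- function(model, age_days, sex) {
  stopifnot(inherits(model, "ms_probe_ref"))
  i <- .grid_index(model$grid, age_days)
  j <- match(sex, ms_sex_levels)
  tibble(mu = model$mu[cbind(i, j)], sigma = model$sigma[cbind(i, j)])
}

#' Fit the reference model for a whole beta matrix
#'
#' Fits [fit_probe_model()] to every probe using the control samples
#' (`class_label == "Normal"`; restricted to `split == "train"` when any
#' sample carries a train/test assignment).
#'
#' @param beta Probes-by-samples beta matrix.
#' @param samples Sample sheet tibble.
#' @param grid Age grid (default [build_age_grid()]).
#' @param k Spline basis dimension.
#' @return List with class `"ms_reference"`: per-sex `mu`/`sigma` arrays
#'   (probes x grid points), `global` tibble, `grid`, `diagnostics` tibble.
#' @export
fit_reference <- function(beta, samples, grid = build_age_grid(), k = 8L) {
  stopifnot(is.matrix(beta), setequal(colnames(beta), samples$sample_id))
  ctrl <- samples[samples$class_label == "Normal", ]
  if (any(samples$split != "unassigned")) ctrl <- ctrl[ctrl$split == "train", ]
  if (nrow(ctrl) < 2L) abort("Need at least 2 control samples to fit a reference.")
  x <- logit(beta[, ctrl$sample_id, drop = FALSE])
  np <- nrow(beta); ng <- length(grid)
  mu_F <- matrix(NA_real_, np, ng); mu_M <- mu_F
  sig_F <- mu_F; sig_M <- mu_F
  global_mu <- numeric(np); global_sigma <- numeric(np)
  degenerate <- logical(np); converged <- logical(np)
  for (i in seq_len(np)) {
    m <- fit_probe_model(x[i, ], ctrl$age_days, ctrl$sex, grid = grid, k = k)
    mu_F[i, ] <- m$mu[, "F"]; mu_M[i, ] <- m$mu[, "M"]
    sig_F[i, ] <- m$sigma[, "F"]; sig_M[i, ] <- m$sigma[, "M"]
    global_mu[i] <- m$global$globalMu; global_sigma[i] <- m$global$globalSigma
    degenerate[i] <- m$global$degenerate; converged[i] <- m$converged
  }
  rownames(mu_F) <- rownames(mu_M) <- rownames(sig_F) <- rownames(sig_M) <- rownames(beta)
  structure(
    list(grid = grid,
         mu = list(F = mu_F, M = mu_M),
         sigma = list(F = sig_F, M = sig_M),
         global = tibble(probe_id = rownames(beta), globalMu = global_mu,
                         globalSigma = global_sigma, degenerate = degenerate),
         diagnostics = tibble(probe_id = rownames(beta),
                              n_controls = nrow(ctrl), converged = converged)),
    class = "ms_reference"
  )
}

#' Serialize / load a fitted reference model
#'
#' Writes one TSV (`probe_id`, `sex`, `age_days`, `mu`, `sigma`; numbers at
#' 17 significant digits so reload is bit-exact) plus a JSON sidecar with
#' the global stats and diagnostics.
#'
#' @param ref An `"ms_reference"`.
#' @param path Path of the TSV; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly (`write_reference`); an `"ms_reference"`
#'   (`read_reference`).
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "ms_reference"))
  probe_ids <- rownames(ref$mu$F)
  ng <- length(ref$grid)
  rows <- purrr::map_dfr(ms_sex_levels, function(sx) {
    tibble(
      probe_id = rep(probe_ids, each = ng),
      sex = sx,
      age_days = rep(ref$grid, times = length(probe_ids)),
      mu = as.vector(t(ref$mu[[sx]])),
      sigma = as.vector(t(ref$sigma[[sx]]))
    )
  })
  rows$mu <- sprintf("%.17g", rows$mu)
  rows$sigma <- sprintf("%.17g", rows$sigma)
  readr::write_tsv(rows, path, progress = FALSE)
  side <- list(
    grid = ref$grid,
    global = list(probe_id = ref$global$probe_id,
                  globalMu = sprintf("%.17g", ref$global$globalMu),
                  globalSigma = sprintf("%.17g", ref$global$globalSigma),
                  degenerate = ref$global$degenerate),
    diagnostics = list(probe_id = ref$diagnostics$probe_id,
                       n_controls = ref$diagnostics$n_controls,
                       converged = ref$diagnostics$converged)
  )
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  rows <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), sex = readr::col_character(),
    age_days = readr::col_integer(), mu = readr::col_character(),
    sigma = readr::col_character()), progress = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- as.integer(side$grid)
  probe_ids <- unique(rows$probe_id)
  ng <- length(grid)
  mu <- list(); sigma <- list()
  for (sx in ms_sex_levels) {
    sub <- rows[rows$sex == sx, ]
    mu[[sx]] <- matrix(as.numeric(sub$mu), nrow = length(probe_ids), ncol = ng,
                       byrow = TRUE, dimnames = list(probe_ids, NULL))
    sigma[[sx]] <- matrix(as.numeric(sub$sigma), nrow = length(probe_ids),
                          ncol = ng, byrow = TRUE, dimnames = list(probe_ids, NULL))
  }
  structure(
    list(grid = grid, mu = mu, sigma = sigma,
         global = tibble(probe_id = side$global$probe_id,
                         globalMu = as.numeric(side$global$globalMu),
                         globalSigma = as.numeric(side$global$globalSigma),
                         degenerate = side$global$degenerate),
         diagnostics = tibble(probe_id = side$diagnostics$probe_id,
                              n_controls = side$diagnostics$n_controls,
                              converged = side$diagnostics$converged)),
    class = "ms_reference"
  )
}
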