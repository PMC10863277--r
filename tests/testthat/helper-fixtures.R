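# Shared fixtures, built in code at test time.

# Small multi-class cohort spec used by several tests.
tiny_cohort_spec <- function(seed = 7L, n_normal = 60L, n_case = 8L,
                             n_probes = 300L) {
  cohort_spec(
    n_per_class = c(Normal = n_normal, BWS1 = n_case, BWS2 = n_case,
                    SRS1 = n_case, AS2 = n_case, PWS1 = n_case,
                    PWS2 = n_case, FXS = n_case),
    n_probes = n_probes, seed = seed
  )
}

# Hand-built z-score panel: probes x samples z matrix -> ms_zpanel tibble
# with all three variants set to the same values (enough for filter /
# region-count tests that look at one variant).
panel_from_matrix <- function(z) {
  out <- tibble::tibble(
    probe_id = rep(rownames(z), times = ncol(z)),
    sample_id = rep(colnames(z), each = nrow(z)),
    z_unadj = as.vector(z), z_adj = as.vector(z), z_reg = as.vector(z),
    p_unadj = p_two_sided(as.vector(z)),
    p_adj = p_two_sided(as.vector(z)),
    p_reg = p_two_sided(as.vector(z))
  )
  class(out) <- c("ms_zpanel", class(out))
  out
}

# Build an ms_reference directly from ground-truth probe models, bypassing
# the fitter: the reference tables contain the exact generative mu/sigma.
# Used to test the scoring path in isolation.
reference_from_truth <- function(models, global_mu, global_sigma,
                                 grid = build_age_grid()) {
  np <- length(models); ng <- length(grid)
  mk <- function(f) {
    m <- t(vapply(models, f, numeric(ng)))
    rownames(m) <- names(models)
    m
  }
  structure(
    list(grid = grid,
         mu = list(F = mk(function(m) truth_mu_(m, grid, "F")),
                   M = mk(function(m) truth_mu_(m, grid, "M"))),
         sigma = list(F = mk(function(m) truth_sigma_(m, grid)),
                      M = mk(function(m) truth_sigma_(m, grid))),
         global = tibble::tibble(probe_id = names(models),
                                 globalMu = global_mu,
                                 globalSigma = global_sigma,
                                 degenerate = FALSE),
         diagnostics = tibble::tibble(probe_id = names(models),
                                      n_controls = NA_integer_,
                                      converged = TRUE)),
    class = "ms_reference"
  )
}

truth_mu_ <- function(m, age_days, sex) {
  m$mu0 + m$age_coef * log1p(age_days / 365.25) + m$sex_offset * (sex == "M")
}
truth_sigma_ <- function(m, age_days) {
  exp(log(m$sigma0) + m$sigma_age_coef * log1p(age_days / 365.25))
}

# The printed 8x8 confusion matrix of the published classifier evaluation
# (rows = predicted, cols = true).
published_confusion <- function() {
  cls <- class_levels()
  m <- matrix(0L, 8, 8, dimnames = list(predicted = cls, true = cls))
  diag(m) <- c(29L, 2L, 3L, 5L, 3L, 3L, 3L, 2L)
  m["Normal", "SRS1"] <- 1L
  m["BWS2", "BWS1"] <- 1L
  m
}
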