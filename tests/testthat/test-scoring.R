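test_that("z-score variants match their closed forms", {
  g <- compute_global_stats(c(-1, 1))  # (0, sqrt(2))
  expect_equal(z_unadjusted(0, g), 0)
  expect_equal(z_unadjusted(3 * sqrt(2), g), 3)
  expect_equal(z_unadjusted(2, g), 2 / sqrt(2), tolerance = 1e-12)

  expect_equal(z_adjusted(1, 1, 0.5), 0)
  expect_equal(z_adjusted(2, 1, 0.5), 2)

  g2 <- list(globalMu = 0, globalSigma = 1)
  expect_equal(z_regularized(2, 2, 0.5, g2, lambda = 0.5), (2 - 1) / 0.75,
               tolerance = 1e-12)
})

test_that("lambda boundaries reduce the regularized score exactly", {
  set.seed(6)
  x <- rnorm(50); mu <- rnorm(50); sigma <- runif(50, 0.2, 2)
  g <- list(globalMu = 0.3, globalSigma = 1.7)
  expect_identical(z_regularized(x, mu, sigma, g, lambda = 1),
                   z_adjusted(x, mu, sigma))
  expect_identical(z_regularized(x, mu, sigma, g, lambda = 0),
                   z_unadjusted(x, g))
  # z_adjusted equals z_unadjusted when handed the global parameters
  expect_identical(z_adjusted(x, g$globalMu, g$globalSigma), z_unadjusted(x, g))
})

test_that("regularized reference parameters interpolate their endpoints", {
  set.seed(13)
  for (i in 1:20) {
    mu <- rnorm(1); sigma <- runif(1, 0.1, 2)
    g <- list(globalMu = rnorm(1), globalSigma = runif(1, 0.1, 2))
    lam <- runif(1)
    mu_reg <- lam * mu + (1 - lam) * g$globalMu
    sigma_reg <- lam * sigma + (1 - lam) * g$globalSigma
    expect_gte(mu_reg, min(mu, g$globalMu))
    expect_lte(mu_reg, max(mu, g$globalMu))
    expect_gte(sigma_reg, min(sigma, g$globalSigma))
    expect_lte(sigma_reg, max(sigma, g$globalSigma))
  }
})

test_that("two-sided p-values follow the standard normal", {
  expect_equal(p_two_sided(0), 1)
  expect_equal(p_two_sided(qnorm(0.975)), 0.05, tolerance = 1e-6)
  expect_equal(p_two_sided(3), 2 * (1 - pnorm(3)), tolerance = 1e-12)
  expect_equal(p_two_sided(3), 0.0027, tolerance = 1e-4)
})

test_that("outlier calls use an inclusive threshold", {
  expect_true(call_outlier(3.0, 3))
  expect_false(call_outlier(-2.99, 3))
  expect_true(call_outlier(-3.5, 3))
  expect_error(call_outlier(1, threshold = 0))
})

test_that("scoring against the exact generative reference is calibrated", {
  # null samples scored against their own generating model: the fraction
  # of |z_adjusted| >= 3 approaches 2 * (1 - pnorm(3)) ~ 0.0027
  models <- list(cg1 = probe_model(-2, 0.6, 0.4, 0.35),
                 cg2 = probe_model(1, -0.3, 0, 0.5))
  n <- 20000L
  demo <- sample_demographics(n, seed = 17L)
  set.seed(17)
  beta <- rbind(cg1 = simulate_probe_values(models$cg1, demo),
                cg2 = simulate_probe_values(models$cg2, demo))
  colnames(beta) <- sprintf("S%05d", seq_len(n))
  samples <- tibble::tibble(sample_id = colnames(beta),
                            age_days = demo$age_days, sex = demo$sex,
                            class_label = "Normal", split = "unassigned")
  ref <- reference_from_truth(models, global_mu = c(0, 0),
                              global_sigma = c(10, 10))
  panel <- score_cohort(beta, samples, ref)
  rate <- mean(abs(panel$z_adj) >= 3)
  p0 <- 2 * (1 - pnorm(3))
  se <- sqrt(p0 * (1 - p0) / (2 * n))
  # grid discretization and boundary clipping add a little extra spread
  expect_lt(abs(rate - p0), 4 * se + 5e-4)
})

test_that("degenerate probes are refused with a warning", {
  beta <- matrix(c(0.5, 0.5, 0.6, 0.7), 2, 2,
                 dimnames = list(c("cg1", "cg2"), c("S1", "S2")))
  models <- list(cg1 = probe_model(0, 0, 0, 0.5),
                 cg2 = probe_model(0, 0, 0, 0.5))
  ref <- reference_from_truth(models, global_mu = c(0, 0),
                              global_sigma = c(1, 1))
  ref$global$degenerate[1] <- TRUE
  samples <- tibble::tibble(sample_id = c("S1", "S2"), age_days = c(100L, 200L),
                            sex = c("F", "M"), class_label = "Normal",
                            split = "unassigned")
  expect_warning(panel <- score_cohort(beta, samples, ref), "degenerate")
  expect_false("cg1" %in% panel$probe_id)
})

test_that("region sensitivity counts outlier probes per sample", {
  z <- matrix(0, 6, 2, dimnames = list(paste0("cg", 1:6), c("S1", "S2")))
  z[1:3, 1] <- 4; z[6, 2] <- -3.2
  panel <- panel_from_matrix(z)
  rs <- region_sensitivity(panel, paste0("cg", 1:5), threshold = 3)
  expect_equal(rs$outlier_count[rs$sample_id == "S1"], 3L)
  expect_equal(rs$outlier_count[rs$sample_id == "S2"], 0L)  # cg6 not in region
  expect_true(all(rs$n_region_probes == 5L))

  expect_error(region_sensitivity(panel, character(0)), "Empty region")
  expect_error(region_sensitivity(panel, c("cg1", "nope")), "absent")
})

test_that("adjustment increases region outlier counts for affected samples", {
  # BWS-like hypomethylation on a 5-probe region over an age-trending locus:
  # the age/sex-adjusted reference should recover at least as many outlier
  # probes as the global one in nearly all replicates
  gt <- lapply(1:5, function(i) probe_model(-1.5, 0.6, 0.3, 0.3))
  names(gt) <- paste0("cg", 1:5)
  wins <- 0L; reps <- 30L
  set.seed(77)
  for (r in seq_len(reps)) {
    demo <- sample_demographics(150)
    beta <- do.call(rbind, lapply(gt, simulate_probe_values, demographics = demo))
    colnames(beta) <- sprintf("S%03d", 1:150)
    samples <- tibble::tibble(sample_id = colnames(beta),
                              age_days = demo$age_days, sex = demo$sex,
                              class_label = "Normal", split = "unassigned")
    # the oldest sample is the patient: at this age-gaining locus its
    # hypomethylated values sit inside the pooled (all-ages) normal range,
    # which is exactly where the global reference goes blind
    case <- which.max(samples$age_days)
    samples$class_label[case] <- "BWS1"   # excluded from the reference fit
    beta[, case] <- apply_effect(beta[, case], 0.3, "hypo")
    ref <- fit_reference(beta, samples, grid = build_age_grid())
    panel <- score_cohort(beta, samples, ref)
    cs <- samples$sample_id[case]
    n_adj <- region_sensitivity(panel, names(gt), cs, "adjusted")$outlier_count
    n_un <- region_sensitivity(panel, names(gt), cs, "unadjusted")$outlier_count
    wins <- wins + (n_adj >= n_un)
  }
  expect_gte(wins / reps, 0.8)
})
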