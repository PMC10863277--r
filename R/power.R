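#' Power-analysis configuration
#'
#' Study conditions for the type-I error / power simulation: at each cohort
#' size, a synthetic control cohort is drawn from the ground-truth probe
#' model (sex fair coin, age uniform 0-85 y), a fresh reference model is
#' fitted to it, and two extra samples are scored — one control draw and
#' one abnormal draw with a constant added on the beta scale. Flagging is
#' two-sided at `alpha` by default (`rule = "p"`); the `|z| >= z_threshold`
#' rule is available via `rule = "z"`.
#'
#' The full-scale protocol (10,000 iterations at every cohort size from 5
#' to 500 in steps of 5) is available by passing those values; the default
#' is a desk-scale profile.
#'
#' @param cohort_sizes Integer cohort sizes (each >= 5).
#' @param iterations Iterations per cohort size (>= 1).
#' @param effect_delta Beta-scale effect size for the abnormal draw.
#' @param alpha Two-sided flagging level.
#' @param lambda Regularization weight for the regularized variant.
#' @param ground_truth An `"ms_probe_truth"` generative model.
#' @param rule `"p"` (p < alpha) or `"z"` (|z| >= z_threshold).
#' @param z_threshold Threshold for `rule = "z"`.
#' @param seed Integer seed.
#' @param epsilon Beta clipping epsilon.
#' @return List with class `"ms_power_config"`.
#' @export
power_config <- function(cohort_sizes = c(10L, 25L, 50L, 100L, 200L),
                         iterations = 2000L,
                         effect_delta = 0.3,
                         alpha = 0.05,
                         lambda = 0.5,
                         ground_truth = default_probe_model(),
                         rule = c("p", "z"),
                         z_threshold = 3,
                         seed = 1L,
                         epsilon = 1e-6) {
  rule <- match.arg(rule)
  stopifnot(all(cohort_sizes >= 5L), iterations >= 1L,
            effect_delta >= 0, alpha > 0, alpha < 1,
            lambda >= 0, lambda <= 1,
            inherits(ground_truth, "ms_probe_truth"))
  structure(
    list(cohort_sizes = as.integer(cohort_sizes),
         iterations = as.integer(iterations),
         effect_delta = effect_delta, alpha = alpha, lambda = lambda,
         ground_truth = ground_truth, rule = rule, z_threshold = z_threshold,
         seed = as.integer(seed), epsilon = epsilon),
    class = "ms_power_config"
  )
}

#' One iteration of the power simulation
#'
#' Draws `n` controls from the ground truth, fits the reference model to
#' them (falling back to the constant global model when the fit is not
#' possible), then draws one control and one effect-injected abnormal test
#' sample and flags each under the three z-score variants. Consumes the
#' current RNG stream; seed at the caller.
#'
#' @param gt An `"ms_probe_truth"`.
#' @param n Cohort size (>= 5).
#' @param delta Beta-scale effect for the abnormal sample.
#' @param lambda Regularization weight.
#' @param alpha Flagging level (`rule = "p"`).
#' @param rule `"p"` or `"z"`.
#' @param z_threshold Threshold for `rule = "z"`.
#' @param epsilon Beta clipping epsilon.
#' @return Named logical vector: `control_/abnormal_` x
#'   `unadjusted/adjusted/regularized`, plus attribute `fallback`.
#' @export
run_power_iteration <- function(gt, n, delta, lambda = 0.5, alpha = 0.05,
                                rule = "p", z_threshold = 3, epsilon = 1e-6) {
  if (n < 5L) abort("Cohort size must be >= 5.")
  demo <- sample_demographics(n + 2L)
  beta <- simulate_probe_values(gt, demo, epsilon = epsilon)
  y <- logit(beta[seq_len(n)])
  ages <- demo$age_days[seq_len(n)]
  sexes <- demo$sex[seq_len(n)]
  global <- compute_global_stats(y)

  test_demo <- demo[n + 1:2, ]
  x_control <- logit(beta[n + 1L])
  x_abnormal <- if (delta > 0) {
    logit(apply_effect(beta[n + 2L], delta, "hyper", epsilon))
  } else logit(beta[n + 2L])  # delta 0: a second null draw

  pred <- NULL
  if (n >= MIN_FIT_N && length(unique(sexes)) == 2L && !global$degenerate) {
    pred <- .fit_locscale(y, ages, sexes)
  }
  fallback <- is.null(pred)
  if (fallback) {
    mu <- rep(global$globalMu, 2L)
    sigma <- rep(max(global$globalSigma, 1e-4), 2L)
  } else {
    # grid-discretized lookup: evaluate at the nearest grid age, as scoring does
    grid <- build_age_grid()
    ga <- grid[.grid_index(grid, test_demo$age_days)]
    pr <- pred(ga, test_demo$sex)
    mu <- pr$mu; sigma <- pr$sigma
  }

  x <- c(x_control, x_abnormal)
  z <- cbind(
    unadjusted = z_unadjusted(x, global),
    adjusted = z_adjusted(x, mu, sigma),
    regularized = z_regularized(x, mu, sigma, global, lambda)
  )
  flags <- if (rule == "p") p_two_sided(z) < alpha else abs(z) >= z_threshold
  out <- c(control = flags[1L, ], abnormal = flags[2L, ])
  attr(out, "fallback") <- fallback
  out
}

#' Run the type-I error and power analysis
#'
#' For each cohort size, repeats [run_power_iteration()] `iterations`
#' times. The type-I error of a variant is the fraction of iterations in
#' which the (truly normal) control draw was flagged; power is the
#' fraction in which the abnormal draw was flagged. With
#' `effect_delta = 0`, power equals type-I error by construction.
#'
#' @param config An `"ms_power_config"`.
#' @param progress Print a line per cohort size.
#' @return Tibble with class `"ms_power"`: `method`, `cohort_size`,
#'   `type1_error`, `power`, `iterations`, `n_fallback`.
#' @export
run_power_analysis <- function(config = power_config(), progress = FALSE) {
  stopifnot(inherits(config, "ms_power_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  res <- purrr::map_dfr(config$cohort_sizes, function(n) {
    acc <- matrix(0L, nrow = config$iterations, ncol = 6L)
    nfb <- 0L
    for (it in seq_len(config$iterations)) {
      fl <- run_power_iteration(config$ground_truth, n, config$effect_delta,
                                lambda = config$lambda, alpha = config$alpha,
                                rule = config$rule,
                                z_threshold = config$z_threshold,
                                epsilon = config$epsilon)
      acc[it, ] <- as.integer(fl)
      nfb <- nfb + as.integer(attr(fl, "fallback"))
    }
    if (progress) message("cohort size ", n, " done")
    rates <- colMeans(acc)
    tibble(
      method = ms_methods,
      cohort_size = n,
      type1_error = rates[1:3],
      power = rates[4:6],
      iterations = config$iterations,
      n_fallback = nfb
    )
  })
  class(res) <- c("ms_power", class(res))
  attr(res, "config") <- config
  res
}

#' Plot type-I error and power curves
#'
#' @param object An `"ms_power"` result.
#' @param ... Ignored.
#' @return A ggplot: curves over cohort size, faceted into type-I error
#'   (with the nominal alpha line) and power panels.
#' @method autoplot ms_power
#' @export
autoplot.ms_power <- function(object, ...) {
  cfg <- attr(object, "config")
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("type1_error", "power"),
                              names_to = "quantity", values_to = "rate")
  long$quantity <- factor(long$quantity, c("type1_error", "power"),
                          c("Type-I error", "Power"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cohort_size, y = .data$rate,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(
      data = tibble(quantity = factor("Type-I error",
                                      c("Type-I error", "Power")),
                    alpha = if (is.null(cfg)) 0.05 else cfg$alpha),
      ggplot2::aes(yintercept = .data$alpha), linetype = "dashed",
      colour = "red") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Cohort size", y = "Rate", colour = "Variant") +
    ggplot2::theme_minimal()
}
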