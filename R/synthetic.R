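#' Ground-truth probe model
#'
#' Generative model for one CpG probe: on the logit scale the value is
#' Normal(mu, sigma) with
#' `mu  = mu0 + age_coef * log(1 + age_years) + sex_offset * [sex == M]` and
#' `log(sigma) = log(sigma0) + sigma_age_coef * log(1 + age_years)`.
#' Betas are the inverse-logit of that draw (a logit-normal), so probe-level
#' age trends are fastest in infancy, matching the day-level resolution the
#' reference grid uses near age 0.
#'
#' @param mu0 Baseline logit-scale mean (age 0, female).
#' @param age_coef Coefficient on `log(1 + age_years)` in the mean.
#' @param sex_offset Additive mean shift for males.
#' @param sigma0 Baseline logit-scale SD (> 0).
#' @param sigma_age_coef Coefficient on `log(1 + age_years)` in log-SD.
#' @return A list with class `"ms_probe_truth"`.
#' @export
probe_model <- function(mu0 = 0, age_coef = 0, sex_offset = 0,
                        sigma0 = 0.5, sigma_age_coef = 0) {
  if (!is.numeric(sigma0) || sigma0 <= 0) abort("sigma0 must be > 0.")
  structure(
    list(mu0 = mu0, age_coef = age_coef, sex_offset = sex_offset,
         sigma0 = sigma0, sigma_age_coef = sigma_age_coef),
    class = "ms_probe_truth"
  )
}

#' Default ground-truth probe for the power analysis
#'
#' A low-methylated probe that gains methylation with age (beta about 0.12
#' at birth rising to about 0.66 at age 85 for females) with a male offset.
#' The effect size used in the power study (+0.3 on the beta scale) stays
#' inside the unit interval for typical samples of this probe, so the three
#' detection variants can genuinely differ; for a highly methylated probe
#' the injected effect saturates at 1 and every variant flags it.
#'
#' @return An `"ms_probe_truth"` object.
#' @export
default_probe_model <- function() {
  probe_model(mu0 = -2.0, age_coef = 0.6, sex_offset = 0.4, sigma0 = 0.35)
}

truth_mu <- function(model, age_days, sex) {
  age_t <- log1p(age_days / DAYS_PER_YEAR)
  model$mu0 + model$age_coef * age_t + model$sex_offset * (sex == "M")
}

truth_sigma <- function(model, age_days) {
  age_t <- log1p(age_days / DAYS_PER_YEAR)
  exp(log(model$sigma0) + model$sigma_age_coef * age_t)
}

#' Random ground-truth probe models
#'
#' Draws probe models covering both age/sex-stable and age/sex-dynamic
#' probes: `mu0 ~ U(-3,3)`, `age_coef ~ U(-0.5,0.5)`, `sex_offset = 0` with
#' probability 0.7 else `U(-1,1)`, `sigma0 ~ U(0.2,0.8)`.
#'
#' @param probe_ids Character vector of probe ids (one model each).
#' @param seed Integer seed.
#' @return Named list of `"ms_probe_truth"` objects.
#' @export
random_probe_models <- function(probe_ids, seed = 1L) {
  n <- length(probe_ids)
  stopifnot(n >= 1L)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  mu0 <- runif(n, -3, 3)
  age_coef <- runif(n, -0.5, 0.5)
  sex_offset <- ifelse(runif(n) < 0.7, 0, runif(n, -1, 1))
  sigma0 <- runif(n, 0.2, 0.8)
  models <- purrr::pmap(list(mu0, age_coef, sex_offset, sigma0),
                        function(m, a, s, g) probe_model(m, a, s, g))
  names(models) <- probe_ids
  models
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Sample cohort demographics
#'
#' Ages uniform on \[0, 85\] years (stored as integer days), sexes
#' independent fair draws of M/F.
#'
#' @param n Number of individuals (>= 1).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (callers inside larger simulations seed once at the top).
#' @return Tibble with columns `age_days` (integer), `sex` (`"F"`/`"M"`).
#' @export
sample_demographics <- function(n, seed = NULL) {
  if (!is.numeric(n) || n < 1) abort("n must be >= 1.")
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
  }
  tibble(
    age_days = as.integer(round(runif(n, 0, 85) * DAYS_PER_YEAR)),
    sex = ifelse(runif(n) < 0.5, "M", "F")
  )
}

#' Simulate beta values for one probe
#'
#' For each individual, draws a logit-scale value from the probe model's
#' Normal(mu(age, sex), sigma(age)) and returns the inverse logit, clipped
#' away from the boundary.
#'
#' @param model An `"ms_probe_truth"` object.
#' @param demographics Tibble with `age_days` and `sex`.
#' @param epsilon Boundary clipping epsilon.
#' @return Numeric vector of beta values in (0,1).
#' @export
simulate_probe_values <- function(model, demographics, epsilon = 1e-6) {
  stopifnot(inherits(model, "ms_probe_truth"), nrow(demographics) >= 1L)
  mu <- truth_mu(model, demographics$age_days, demographics$sex)
  sigma <- truth_sigma(model, demographics$age_days)
  if (any(sigma <= 0)) abort("Probe model implies non-positive sigma.")
  clip_beta(inv_logit(rnorm(nrow(demographics), mu, sigma)), epsilon)
}

#' Inject a methylation effect into a beta value
#'
#' Adds (`hyper`) or subtracts (`hypo`) a constant on the beta scale,
#' clipping into `[epsilon, 1 - epsilon]`.
#'
#' @param beta Numeric beta values in (0,1).
#' @param delta Effect size on the beta scale (> 0).
#' @param direction `"hyper"` or `"hypo"`.
#' @param epsilon Boundary clipping epsilon.
#' @return Shifted beta values.
#' @examples
#' apply_effect(0.5, 0.3, "hyper") # 0.8
#' @export
apply_effect <- function(beta, delta, direction = c("hyper", "hypo"),
                         epsilon = 1e-6) {
  direction <- match.arg(direction)
  stopifnot(delta > 0, all(beta > 0), all(beta < 1))
  if (direction == "hyper") pmin(beta + delta, 1 - epsilon)
  else pmax(beta - delta, epsilon)
}

#' Disorder effect specification
#'
#' Describes how one disorder class perturbs methylation: a constant
#' beta-scale shift applied to the probes of a named region (regional
#' disorders), or — with `region_name = "global"` — to a per-sample random
#' fraction of all probes (the diffuse, heterogeneous signature seen in
#' Silver-Russell syndrome). For `"global"` specs `direction` may be
#' `"random"`, choosing hyper/hypo independently per affected probe.
#'
#' @param class_label Affected class label.
#' @param region_name Region name in the cohort's region set, or `"global"`.
#' @param direction `"hyper"`, `"hypo"`, or `"random"` (global only).
#' @param effect_delta Beta-scale shift in (0,1).
#' @param fraction_probes_affected Fraction of probes hit (1 for regional
#'   disorders; < 1 for diffuse signatures).
#' @return A list with class `"ms_disease_spec"`.
#' @export
disease_spec <- function(class_label, region_name, direction, effect_delta,
                         fraction_probes_affected = 1) {
  stopifnot(effect_delta > 0, effect_delta < 1,
            fraction_probes_affected > 0, fraction_probes_affected <= 1)
  if (!direction %in% c("hyper", "hypo", "random")) abort("Bad direction.")
  if (direction == "random" && region_name != "global") {
    abort("direction = 'random' is only meaningful for region_name = 'global'.")
  }
  structure(
    list(class_label = class_label, region_name = region_name,
         direction = direction, effect_delta = effect_delta,
         fraction_probes_affected = fraction_probes_affected),
    class = "ms_disease_spec"
  )
}

#' Default disorder-region layout
#'
#' Five target loci totalling 98 probes, mirroring the probe counts of a
#' clinically curated target panel: an H19-like region (16 probes), a
#' KCNQ1OT1/LIT1-like region (24), an SNRPN/SNURF-like region (20), an
#' MKRN3-like region (14, covering the broader type-1 deletion extent),
#' and an FMR1-like region (24). Regions occupy the first 98 probe ids of
#' the cohort; remaining probes are background.
#'
#' @param probe_ids All probe ids of the cohort (>= 98).
#' @return Named list of probe-id vectors.
#' @export
default_region_set <- function(probe_ids) {
  sizes <- c(H19 = 16L, KCNQ1OT1 = 24L, SNRPN = 20L, MKRN3 = 14L, FMR1 = 24L)
  if (length(probe_ids) < sum(sizes)) abort("Need at least 98 probes for the default regions.")
  out <- list(); start <- 1L
  for (nm in names(sizes)) {
    out[[nm]] <- probe_ids[start:(start + sizes[[nm]] - 1L)]
    start <- start + sizes[[nm]]
  }
  out
}

#' Default disorder effect specifications
#'
#' Encodes the expected hyper-/hypomethylation patterns of the seven
#' disorder classes against the [default_region_set()] loci:
#' * BWS1 - H19 hypermethylation plus KCNQ1OT1 hypomethylation;
#' * BWS2 - KCNQ1OT1 hypomethylation only;
#' * SRS1 - diffuse signature: a random 10% of all probes per sample,
#'   shifted by 0.15 in a random direction (high inter-patient
#'   heterogeneity, no canonical locus);
#' * AS2  - SNRPN hypomethylation;
#' * PWS1 - SNRPN plus MKRN3 hypermethylation (broader deletion extent);
#' * PWS2 - SNRPN hypermethylation;
#' * FXS  - FMR1 hypermethylation.
#'
#' @param effect_delta Regional beta-scale shift (default 0.3).
#' @return List of `"ms_disease_spec"` objects.
#' @export
default_disease_specs <- function(effect_delta = 0.3) {
  list(
    disease_spec("BWS1", "H19", "hyper", effect_delta),
    disease_spec("BWS1", "KCNQ1OT1", "hypo", effect_delta),
    disease_spec("BWS2", "KCNQ1OT1", "hypo", effect_delta),
    disease_spec("SRS1", "global", "random", 0.15, fraction_probes_affected = 0.1),
    disease_spec("AS2", "SNRPN", "hypo", effect_delta),
    disease_spec("PWS1", "SNRPN", "hyper", effect_delta),
    disease_spec("PWS1", "MKRN3", "hyper", effect_delta),
    disease_spec("PWS2", "SNRPN", "hyper", effect_delta),
    disease_spec("FXS", "FMR1", "hyper", effect_delta)
  )
}

#' Synthetic cohort specification
#'
#' Bundles everything [generate_cohort()] needs. Defaults give a cohort of
#' 150 controls plus 15 samples of each of the seven disorder classes over
#' 2,000 probes with the default region layout and disease effects.
#'
#' @param n_per_class Named integer vector, class label -> count. Classes
#'   absent from the vector get zero samples.
#' @param n_probes Number of probes.
#' @param regions Named list of probe-id vectors (default
#'   [default_region_set()]).
#' @param probe_models Named list of `"ms_probe_truth"`, one per probe
#'   (default [random_probe_models()] under `seed`).
#' @param disease_specs List of `"ms_disease_spec"` (default
#'   [default_disease_specs()]).
#' @param seed Integer seed controlling every draw.
#' @param epsilon Beta clipping epsilon.
#' @return A list with class `"ms_cohort_spec"`.
#' @export
cohort_spec <- function(n_per_class = c(Normal = 150L, BWS1 = 15L, BWS2 = 15L,
                                        SRS1 = 15L, AS2 = 15L, PWS1 = 15L,
                                        PWS2 = 15L, FXS = 15L),
                        n_probes = 2000L,
                        regions = NULL,
                        probe_models = NULL,
                        disease_specs = default_disease_specs(),
                        seed = 1L,
                        epsilon = 1e-6) {
  stopifnot(all(n_per_class >= 0L), n_probes >= 1L)
  probe_ids <- sprintf("cg%06d", seq_len(n_probes))
  regions <- regions %||% default_region_set(probe_ids)
  probe_models <- probe_models %||% random_probe_models(probe_ids, seed = seed)
  if (!setequal(names(probe_models), probe_ids)) {
    abort("probe_models must be named by the cohort's probe ids.")
  }
  .check_regions(regions, probe_ids)
  for (ds in disease_specs) {
    if (ds$region_name != "global" && !ds$region_name %in% names(regions)) {
      abort(paste0("Disease spec references unknown region '", ds$region_name, "'."))
    }
  }
  structure(
    list(n_per_class = n_per_class, n_probes = as.integer(n_probes),
         probe_ids = probe_ids, regions = regions,
         probe_models = probe_models[probe_ids], disease_specs = disease_specs,
         seed = as.integer(seed), epsilon = epsilon),
    class = "ms_cohort_spec"
  )
}

#' Generate a synthetic methylation cohort
#'
#' Draws demographics for every sample, simulates each probe from its
#' ground-truth model, then applies the disorder effects: regional specs
#' shift the region's probes in all samples of the class; `"global"` specs
#' shift a per-sample random subset of probes (random direction per probe
#' when requested), emulating heterogeneous diffuse signatures. The whole
#' construction is deterministic given `spec$seed`.
#'
#' @param spec An `"ms_cohort_spec"`.
#' @return List with elements `beta` (probes x samples matrix), `samples`
#'   (tibble: sample_id, age_days, sex, class_label, split) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ms_cohort_spec"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(spec$seed)

  counts <- spec$n_per_class[spec$n_per_class > 0L]
  n <- sum(counts)
  samples <- sample_demographics(n)
  samples$sample_id <- sprintf("S%04d", seq_len(n))
  samples$class_label <- rep(names(counts), counts)
  samples$split <- "unassigned"
  samples <- samples[, c("sample_id", "age_days", "sex", "class_label", "split")]

  beta <- matrix(NA_real_, nrow = spec$n_probes, ncol = n,
                 dimnames = list(spec$probe_ids, samples$sample_id))
  for (i in seq_len(spec$n_probes)) {
    beta[i, ] <- simulate_probe_values(spec$probe_models[[i]], samples,
                                       epsilon = spec$epsilon)
  }

  for (ds in spec$disease_specs) {
    cols <- which(samples$class_label == ds$class_label)
    if (!length(cols)) next
    if (ds$region_name == "global") {
      n_hit <- max(1L, round(ds$fraction_probes_affected * spec$n_probes))
      for (j in cols) {
        hit <- sample.int(spec$n_probes, n_hit)
        dir <- if (ds$direction == "random") {
          ifelse(runif(n_hit) < 0.5, "hyper", "hypo")
        } else rep(ds$direction, n_hit)
        for (d in c("hyper", "hypo")) {
          rows <- hit[dir == d]
          if (length(rows)) {
            beta[rows, j] <- apply_effect(beta[rows, j], ds$effect_delta, d,
                                          spec$epsilon)
          }
        }
      }
    } else {
      rows <- match(spec$regions[[ds$region_name]], spec$probe_ids)
      beta[rows, cols] <- apply_effect(beta[rows, cols], ds$effect_delta,
                                       ds$direction, spec$epsilon)
    }
  }
  list(beta = beta, samples = samples, spec = spec)
}
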