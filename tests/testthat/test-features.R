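test_that("stratified split assigns round(fraction * class size) to train", {
  samples <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:20),
    age_days = 1000L, sex = "F",
    class_label = rep(c("Normal", "PWS1"), each = 10L),
    split = "unassigned"
  )
  sp <- split_train_test(samples, 0.8, seed = 1L)
  tab <- table(sp$class_label, sp$split)
  expect_equal(unname(tab["Normal", "train"]), 8)
  expect_equal(unname(tab["PWS1", "train"]), 8)
  expect_equal(unname(tab["Normal", "test"]), 2)

  nine <- tibble::tibble(sample_id = sprintf("T%02d", 1:9), age_days = 1L,
                         sex = "M", class_label = "FXS", split = "unassigned")
  sp9 <- split_train_test(nine, 0.8, seed = 2L)
  expect_equal(sum(sp9$split == "train"), 7L)  # round(0.8 * 9)

  expect_identical(split_train_test(samples, 0.8, seed = 5L),
                   split_train_test(samples, 0.8, seed = 5L))

  single <- tibble::tibble(sample_id = "X", age_days = 1L, sex = "F",
                           class_label = "AS2", split = "unassigned")
  expect_error(split_train_test(rbind(samples, single)), ">= 2")
})

test_that("z-filter survivors match an exhaustive scan", {
  set.seed(14)
  z <- matrix(rnorm(10 * 8, sd = 1.6), 10, 8,
              dimnames = list(paste0("cg", 1:10), paste0("S", 1:8)))
  panel <- panel_from_matrix(z)
  train <- paste0("S", 1:5)
  for (ms in c(1L, 2L)) {
    got <- filter_probes_by_z(panel, train, threshold = 3, min_samples = ms)
    want <- rownames(z)[rowSums(abs(z[, train]) >= 3) >= ms]
    expect_identical(got, want)
  }
  # probe with a single just-over-threshold sample is kept at min_samples 1
  z2 <- matrix(0, 2, 3, dimnames = list(c("a", "b"), c("S1", "S2", "S3")))
  z2["a", 2] <- 3.2
  expect_identical(filter_probes_by_z(panel_from_matrix(z2), threshold = 3),
                   "a")
})

test_that("target features de-duplicate shared probes and respect the filter", {
  z <- matrix(seq_len(10), 5, 2,
              dimnames = list(paste0("cg", 1:5), c("S1", "S2")))
  panel <- panel_from_matrix(z)
  regions <- list(R1 = c("cg1", "cg2", "cg3"), R2 = c("cg3", "cg4", "cg5"))
  f <- extract_target_features(panel, regions, passing_ids = paste0("cg", 1:5))
  expect_equal(colnames(f), paste0("cg", 1:5))  # cg3 once, first occurrence
  expect_equal(dim(f), c(2L, 5L))
  f2 <- extract_target_features(panel, regions, passing_ids = c("cg2", "cg4"))
  expect_equal(colnames(f2), c("cg2", "cg4"))
  expect_error(extract_target_features(panel, regions, passing_ids = "cg9"),
               "passed")
})

test_that("umap embeds separated clusters separably and projects new points", {
  set.seed(19)
  centers <- matrix(rnorm(3 * 12, sd = 6), 3, 12)
  x <- centers[rep(1:3, each = 20), ] + matrix(rnorm(60 * 12, sd = 0.3), 60, 12)
  rownames(x) <- sprintf("S%02d", 1:60)
  fit <- umap_global_features(x, n_dims = 2L, seed = 33L)
  expect_equal(dim(fit$embedding), c(60L, 2L))
  expect_equal(colnames(fit$embedding), c("umap_1", "umap_2"))
  # cluster-quality: mean silhouette over the known 3-cluster labeling
  lab <- rep(1:3, each = 20)
  d <- as.matrix(dist(fit$embedding))
  sil <- vapply(1:60, function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(60) != i])
    b <- min(vapply(setdiff(1:3, lab[i]),
                    function(k) mean(d[i, lab == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  # projecting training points lands near their embedded coordinates
  proj <- umap_project(x, fit)
  expect_equal(dim(proj), dim(fit$embedding))
  spread <- mean(apply(fit$embedding, 2, sd))
  err <- sqrt(rowSums((proj - fit$embedding)^2))
  expect_lt(stats::median(err), spread)
  # same seed, same embedding
  fit2 <- umap_global_features(x, n_dims = 2L, seed = 33L)
  expect_equal(fit$embedding, fit2$embedding)
})

test_that("umap refuses too-few samples for the requested dimensionality", {
  x <- matrix(rnorm(50), 10, 5)
  rownames(x) <- paste0("S", 1:10)
  expect_error(umap_global_features(x, n_dims = 20L), "reduce n_dims")
})

test_that("correlation pruning removes duplicates and satisfies its postcondition", {
  set.seed(23)
  a <- rnorm(40); c_ <- rnorm(40)
  x <- cbind(A = a, B = a, C = c_)
  # A and B are identical so their mean absolute correlations tie; the later
  # column (B) is dropped and the independent C survives
  kept <- prune_correlated(x, 0.9)
  expect_equal(kept, c("A", "C"))
  cm <- abs(cor(x[, kept])); diag(cm) <- 0
  expect_lte(max(cm), 0.9)
})

test_that("pruning survivors never contain an over-cutoff pair", {
  set.seed(29)
  for (r in 1:10) {
    n <- 30L; p <- 8L
    base <- matrix(rnorm(n * p), n, p)
    # induce correlated blocks
    base[, 2] <- base[, 1] + rnorm(n, sd = 0.1)
    base[, 5] <- base[, 4] + rnorm(n, sd = 0.05)
    colnames(base) <- paste0("f", seq_len(p))
    kept <- prune_correlated(base, 0.9)
    cm <- abs(cor(base[, kept, drop = FALSE]))
    diag(cm) <- 0
    expect_lte(max(cm), 0.9)
    expect_identical(kept, colnames(base)[colnames(base) %in% kept])  # order
  }
})

test_that("pruning leaves uncorrelated features untouched and drops constants", {
  set.seed(31)
  x <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  expect_equal(prune_correlated(x, 0.999999), colnames(x))
  xc <- cbind(x, konst = 1)
  expect_warning(kept <- prune_correlated(xc, 0.9), "zero-variance")
  expect_false("konst" %in% kept)
})

test_that("feature assembly concatenates blocks and restricts to retained", {
  tgt <- matrix(1, 3, 2, dimnames = list(c("S1", "S2", "S3"), c("cg1", "cg2")))
  um <- matrix(2, 3, 2, dimnames = list(c("S1", "S2", "S3"),
                                        c("umap_1", "umap_2")))
  all4 <- assemble_features(tgt, um)
  expect_equal(colnames(all4), c("cg1", "cg2", "umap_1", "umap_2"))
  sub <- assemble_features(tgt, um, retained = c("cg2", "umap_1"))
  expect_equal(colnames(sub), c("cg2", "umap_1"))
  bad <- um; colnames(bad) <- c("cg1", "umap_2")
  expect_error(assemble_features(tgt, bad), "collision")
  expect_error(assemble_features(tgt, um, retained = "nope"), "Unknown")
})

test_that("feature selection never uses test samples", {
  set.seed(37)
  n_train <- 40L; n_test <- 10L
  probes <- paste0("cg", 1:60)
  ids <- c(sprintf("TR%02d", 1:n_train), sprintf("TE%02d", 1:n_test))
  z <- matrix(rnorm(60 * 50), 60, 50, dimnames = list(probes, ids))
  z[1:10, 1:12] <- z[1:10, 1:12] + 5   # strong signal in some train samples
  samples <- tibble::tibble(
    sample_id = ids, age_days = 2000L, sex = "F",
    class_label = rep(c("Normal", "PWS1"), 25),
    split = rep(c("train", "test"), c(n_train, n_test))
  )
  regions <- list(R1 = paste0("cg", 1:5))
  cfg <- pipeline_config(seed = 5L, umap_dims = 4L)

  full <- build_features(panel_from_matrix(z), samples, regions, cfg)
  train_only <- build_features(
    panel_from_matrix(z[, 1:n_train]), samples[1:n_train, ], regions, cfg
  )
  expect_identical(full$state$passing_probe_ids,
                   train_only$state$passing_probe_ids)
  expect_identical(full$state$retained, train_only$state$retained)
  expect_equal(full$state$umap_fit$embedding,
               train_only$state$umap_fit$embedding)
  expect_identical(full$train, train_only$train)
})
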