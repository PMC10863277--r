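# Two interleaved Gaussian blobs in 2D, plus helpers for oof tests.
make_blobs <- function(n_per = 50L, seed = 1L, sd = 0.5) {
  set.seed(seed)
  x <- rbind(
    cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
    cbind(rnorm(n_per, 3, sd), rnorm(n_per, 3, sd))
  )
  colnames(x) <- c("f1", "f2")
  rownames(x) <- sprintf("S%03d", seq_len(2 * n_per))
  list(x = x, y = rep(c("Normal", "PWS1"), each = n_per))
}

test_that("bagged training gives every sample exactly one out-of-fold row", {
  b <- make_blobs(50L, seed = 3L)
  bag <- train_bagged(b$x, b$y, k = 5L,
                      learners = base_learners("random_forest"), seed = 2L)
  oof <- bag$learners$random_forest$oof
  expect_false(anyNA(oof))
  expect_equal(unname(rowSums(oof)), rep(1, 100), tolerance = 1e-9)
  expect_equal(sort(unique(bag$fold_id)), 1:5)
  # stratification: both classes in every fold
  for (f in 1:5) expect_equal(length(unique(b$y[bag$fold_id == f])), 2L)
})

test_that("separable blobs reach high out-of-fold accuracy", {
  b <- make_blobs(50L, seed = 5L)
  bag <- train_bagged(b$x, b$y, k = 5L,
                      learners = base_learners("gradient_boosted_trees"),
                      seed = 4L)
  oof <- bag$learners$gradient_boosted_trees$oof
  acc <- mean(class_levels()[apply(oof, 1, which.max)] == b$y)
  expect_gt(acc, 0.9)
})

test_that("training is deterministic under a seed", {
  b <- make_blobs(30L, seed = 7L)
  e1 <- train_ensemble(b$x, b$y, k = 3L, seed = 11L)
  e2 <- train_ensemble(b$x, b$y, k = 3L, seed = 11L)
  expect_identical(e1$weights, e2$weights)
  expect_identical(predict(e1, b$x), predict(e2, b$x))
})

test_that("greedy weighting concentrates on a dominant learner", {
  set.seed(41)
  n <- 120L
  y <- rep(class_levels()[1:4], each = 30L)
  perfect <- matrix(0, n, 8, dimnames = list(NULL, class_levels()))
  perfect[cbind(seq_len(n), match(y, class_levels()))] <- 1
  noise1 <- matrix(runif(n * 8), n, 8); noise1 <- noise1 / rowSums(noise1)
  noise2 <- matrix(runif(n * 8), n, 8); noise2 <- noise2 / rowSums(noise2)
  colnames(noise1) <- colnames(noise2) <- class_levels()
  w <- fit_ensemble_weights(list(na = noise1, good = perfect, nb = noise2), y)
  expect_gte(w[["good"]], 0.9)
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))

  # single learner gets weight one
  w1 <- fit_ensemble_weights(list(only = noise1), y)
  expect_equal(unname(w1), 1)

  # identical learners: the ensemble probabilities equal either one's
  w2 <- fit_ensemble_weights(list(a = perfect, b = perfect), y)
  mix <- w2[["a"]] * perfect + w2[["b"]] * perfect
  expect_equal(mix, perfect)
})

test_that("ensemble out-of-fold accuracy weakly dominates each learner", {
  b <- make_blobs(40L, seed = 13L)
  ens <- train_ensemble(b$x, b$y, k = 4L, seed = 17L)
  expect_gte(ens$oof_accuracy, max(ens$learner_oof_accuracy) - 1e-12)
})

test_that("prediction applies weights, tie-breaks, and validates columns", {
  b <- make_blobs(30L, seed = 19L)
  ens <- train_ensemble(b$x, b$y, k = 3L,
                        learners = base_learners(c("random_forest",
                                                   "k_nearest_neighbors")),
                        seed = 23L)
  pred <- predict(ens, b$x)
  expect_equal(nrow(pred), 60L)
  probs <- as.matrix(pred[, paste0("prob_", class_levels())])
  expect_equal(unname(rowSums(probs)), rep(1, 60), tolerance = 1e-9)
  expect_true(all(pred$predicted_prob >= pred$runner_up_prob))
  # training accuracy on separable blobs is essentially perfect
  expect_gt(mean(pred$predicted == b$y), 0.97)

  bad <- b$x[, 1, drop = FALSE]
  expect_error(predict(ens, bad), "mismatch")

  # forcing all weight on one learner reproduces its fold-averaged output
  ens1 <- ens
  ens1$weights <- c(random_forest = 1, k_nearest_neighbors = 0)
  p1 <- predict(ens1, b$x)
  impl_avg <- Reduce(`+`, lapply(ens$bag$learners$random_forest$models,
    function(m) {
      d <- as.data.frame(b$x)
      pr <- predict(m$rf, data = d, num.threads = 1L)$predictions
      out <- matrix(0, nrow(b$x), 8, dimnames = list(rownames(b$x), class_levels()))
      out[, colnames(pr)] <- pr
      out
    })) / ens$bag$k
  expect_equal(as.matrix(p1[, paste0("prob_", class_levels())]),
               unname(impl_avg), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("uniform probabilities predict the first class in order", {
  p <- matrix(1 / 8, 2, 8, dimnames = list(c("a", "b"), class_levels()))
  expect_equal(methylscreen:::.argmax_label(p, class_levels()),
               c("Normal", "Normal"))
})

test_that("single-class input and tiny classes are handled", {
  b <- make_blobs(10L, seed = 29L)
  expect_error(train_bagged(b$x, rep("Normal", 20L)), "two classes")
  y_small <- c(rep("Normal", 17L), rep("FXS", 3L))
  expect_warning(bag <- train_bagged(b$x, y_small, k = 5L,
                                     learners = base_learners("k_nearest_neighbors"),
                                     seed = 1L),
                 "reducing folds")
  expect_equal(bag$k, 3L)
})

test_that("tidy and glance summarise the ensemble", {
  b <- make_blobs(25L, seed = 31L)
  ens <- train_ensemble(b$x, b$y, k = 3L,
                        learners = base_learners(c("random_forest",
                                                   "multinomial_logistic")),
                        seed = 2L)
  td <- generics::tidy(ens)
  expect_equal(td$learner, c("random_forest", "multinomial_logistic"))
  expect_equal(sum(td$weight), 1)
  gl <- generics::glance(ens)
  expect_equal(gl$n_learners, 2L)
  expect_equal(gl$k_folds, 3L)
})
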