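# Base-learner registry. Each entry: fit(x, y, class_order, seed) -> model,
# predict(model, x) -> samples x classes probability matrix (columns in
# class_order, rows summing to 1).

.learner_gbt <- list(
  fit = function(x, y, class_order, seed, params = list()) {
    lab <- as.integer(factor(y, levels = class_order)) - 1L
    dm <- xgboost::xgb.DMatrix(x, label = lab, nthread = 1L)
    bst <- xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(class_order),
                    max_depth = params$max_depth %||% 3L,
                    eta = params$eta %||% 0.3,
                    nthread = 1L, seed = seed),
      data = dm, nrounds = params$nrounds %||% 60L, verbose = 0
    )
    list(bst = bst, class_order = class_order)
  },
  predict = function(model, x) {
    p <- predict(model$bst, xgboost::xgb.DMatrix(x, nthread = 1L))
    p <- matrix(as.numeric(p), nrow = nrow(x),
                ncol = length(model$class_order),
                dimnames = list(rownames(x), model$class_order))
    p
  }
)

.learner_rf <- list(
  fit = function(x, y, class_order, seed, params = list()) {
    d <- as.data.frame(x)
    # only observed levels: ranger refuses empty classes in a probability forest
    d$.y <- factor(y, levels = intersect(class_order, unique(y)))
    rf <- ranger::ranger(dependent.variable.name = ".y", data = d,
                         num.trees = params$num_trees %||% 300L,
                         probability = TRUE, seed = seed, num.threads = 1L)
    list(rf = rf, class_order = class_order)
  },
  predict = function(model, x) {
    p <- predict(model$rf, data = as.data.frame(x),
                 num.threads = 1L)$predictions
    .reindex_prob(p, model$class_order, rownames(x))
  }
)

.learner_knn <- list(
  fit = function(x, y, class_order, seed, params = list()) {
    mu <- colMeans(x); sg <- apply(x, 2L, sd); sg[sg == 0] <- 1
    list(x = scale(x, mu, sg), y = y, k = params$k %||% 5L,
         mu = mu, sg = sg, class_order = class_order)
  },
  predict = function(model, x) {
    xs <- scale(x, model$mu, model$sg)
    k <- min(model$k, nrow(model$x))
    nn <- FNN::get.knnx(model$x, xs, k = k)$nn.index
    out <- matrix(0, nrow(x), length(model$class_order),
                  dimnames = list(rownames(x), model$class_order))
    for (i in seq_len(nrow(x))) {
      votes <- table(factor(model$y[nn[i, ]], levels = model$class_order))
      out[i, ] <- as.numeric(votes) / k
    }
    out
  }
)

.learner_mlr <- list(
  fit = function(x, y, class_order, seed, params = list()) {
    d <- as.data.frame(x)
    d$.y <- factor(y, levels = intersect(class_order, unique(y)))
    set.seed(seed)
    fit <- nnet::multinom(.y ~ ., data = d, trace = FALSE, maxit = 200L,
                          decay = params$decay %||% 0.01,
                          MaxNWts = 100000L)
    list(fit = fit, levels = levels(d$.y), class_order = class_order)
  },
  predict = function(model, x) {
    p <- predict(model$fit, newdata = as.data.frame(x), type = "probs")
    if (is.null(dim(p))) {  # two-class fits return a vector for the 2nd level
      p <- cbind(1 - p, p)
      colnames(p) <- model$levels
    }
    .reindex_prob(p, model$class_order, rownames(x))
  }
)

.reindex_prob <- function(p, class_order, row_names) {
  out <- matrix(0, nrow(p), length(class_order),
                dimnames = list(row_names, class_order))
  shared <- intersect(colnames(p), class_order)
  out[, shared] <- p[, shared, drop = FALSE]
  out / pmax(rowSums(out), .Machine$double.eps)
}

.learner_registry <- list(
  gradient_boosted_trees = .learner_gbt,
  random_forest = .learner_rf,
  k_nearest_neighbors = .learner_knn,
  multinomial_logistic = .learner_mlr
)

#' Base-learner specifications
#'
#' The registered learner families standing behind the weighted ensemble:
#' gradient-boosted trees, random forest, k-nearest neighbors, and
#' multinomial logistic regression.
#'
#' @param names Subset of the registered learner names.
#' @param params Optional named list of per-learner hyperparameter lists.
#' @return Named list of learner specs.
#' @export
base_learners <- function(names = c("gradient_boosted_trees", "random_forest",
                                    "k_nearest_neighbors",
                                    "multinomial_logistic"),
                          params = list()) {
  bad <- setdiff(names, names(.learner_registry))
  if (length(bad)) abort(paste0("Unknown learner(s): ", paste(bad, collapse = ", ")))
  out <- lapply(names, function(nm) list(name = nm, params = params[[nm]] %||% list()))
  stats::setNames(out, names)
}

# Stratified k-fold assignment: within each class, shuffled samples are
# dealt round-robin into folds.
.stratified_folds <- function(y, k, seed) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Bagged k-fold training of the base learners
#'
#' Stratified k-fold partition of the training samples; each learner is
#' fitted k times on k-1 folds, collecting an out-of-fold class-probability
#' row for every training sample. Prediction-time probabilities average
#' the k fold-models. If the smallest class has fewer members than `k`,
#' `k` is reduced with a warning.
#'
#' @param x Samples-by-features numeric training matrix (rownames = ids).
#' @param y Class labels (character) aligned with rows of `x`.
#' @param k Number of folds (default 5).
#' @param learners Learner specs from [base_learners()].
#' @param class_order Fixed label ordering.
#' @param seed Integer seed.
#' @return List: per-learner `folds` (models), `oof` (out-of-fold
#'   probability matrices), plus `fold_id`, `k`, `class_order`.
#' @export
train_bagged <- function(x, y, k = 5L, learners = base_learners(),
                         class_order = ms_class_levels, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y), k >= 2L)
  if (length(unique(y)) < 2L) abort("Need at least two classes to train.")
  min_class <- min(table(y))
  if (min_class < k) {
    warn(sprintf("Smallest class has %d samples; reducing folds from %d to %d.",
                 min_class, k, max(2L, min_class)))
    k <- max(2L, as.integer(min_class))
  }
  fold_id <- .stratified_folds(y, k, seed)
  fitted <- purrr::imap(learners, function(spec, nm) {
    impl <- .learner_registry[[spec$name]]
    oof <- matrix(NA_real_, nrow(x), length(class_order),
                  dimnames = list(rownames(x), class_order))
    models <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- fold_id != f
      models[[f]] <- impl$fit(x[tr, , drop = FALSE], y[tr], class_order,
                              seed = seed + f, params = spec$params)
      oof[!tr, ] <- impl$predict(models[[f]], x[!tr, , drop = FALSE])
    }
    list(name = spec$name, models = models, oof = oof)
  })
  list(learners = fitted, fold_id = fold_id, k = k, class_order = class_order)
}

#' Greedy weighted-ensemble selection
#'
#' Caruana-style forward selection with replacement on the out-of-fold
#' probabilities: over `rounds` rounds, repeatedly add the learner whose
#' inclusion maximises out-of-fold accuracy of the running probability
#' average; the best ensemble seen is kept, so its training-objective
#' accuracy weakly dominates every single learner. Weights are selection
#' frequencies.
#'
#' @param oof_list Named list of out-of-fold probability matrices.
#' @param y True labels for the training samples.
#' @param class_order Label ordering (argmax ties break to earlier class).
#' @param rounds Selection rounds (default 25).
#' @return Named numeric weights (>= 0, summing to 1).
#' @export
fit_ensemble_weights <- function(oof_list, y, class_order = ms_class_levels,
                                 rounds = 25L) {
  stopifnot(length(oof_list) >= 1L, rounds >= 1L)
  acc_of <- function(p) mean(.argmax_label(p, class_order) == y)
  counts <- stats::setNames(integer(length(oof_list)), names(oof_list))
  sum_p <- matrix(0, nrow(oof_list[[1L]]), ncol(oof_list[[1L]]))
  best <- list(acc = -Inf, counts = counts)
  for (r in seq_len(rounds)) {
    accs <- vapply(oof_list, function(p) acc_of((sum_p + p) / r), numeric(1L))
    pick <- which.max(accs)
    counts[pick] <- counts[pick] + 1L
    sum_p <- sum_p + oof_list[[pick]]
    if (accs[pick] > best$acc) best <- list(acc = accs[pick], counts = counts)
  }
  w <- best$counts / sum(best$counts)
  w
}

.argmax_label <- function(p, class_order) {
  class_order[apply(p, 1L, which.max)]  # which.max: first maximum wins
}

#' Train the bagged weighted ensemble
#'
#' Runs [train_bagged()] then [fit_ensemble_weights()] and packages the
#' result for prediction.
#'
#' @inheritParams train_bagged
#' @param rounds Greedy-selection rounds.
#' @return Object of class `"ms_ensemble"`.
#' @export
train_ensemble <- function(x, y, k = 5L, learners = base_learners(),
                           class_order = ms_class_levels, seed = 1L,
                           rounds = 25L) {
  bag <- train_bagged(x, y, k = k, learners = learners,
                      class_order = class_order, seed = seed)
  oof_list <- purrr::map(bag$learners, "oof")
  weights <- fit_ensemble_weights(oof_list, y, class_order, rounds = rounds)
  ens_oof <- Reduce(`+`, purrr::map2(oof_list, weights, `*`))
  structure(
    list(bag = bag, weights = weights, class_order = class_order,
         feature_names = colnames(x),
         oof_accuracy = mean(.argmax_label(ens_oof, class_order) == y),
         learner_oof_accuracy = vapply(oof_list, function(p) {
           mean(.argmax_label(p, class_order) == y)
         }, numeric(1L))),
    class = "ms_ensemble"
  )
}

#' Predict classes with a trained ensemble
#'
#' Per-learner probabilities are the mean over the k fold-models; the
#' ensemble probability is their weighted sum. The predicted label is the
#' argmax (ties break to the earlier class in `class_order`).
#'
#' @param object An `"ms_ensemble"`.
#' @param newdata Samples-by-features matrix with exactly the training
#'   feature columns.
#' @param ... Ignored.
#' @return Tibble: `sample_id`, `predicted`, `runner_up`,
#'   `predicted_prob`, `runner_up_prob`, plus one `prob_<class>` column
#'   per class.
#' @export
predict.ms_ensemble <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  missing <- setdiff(object$feature_names, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$feature_names)
  if (length(missing) || length(extra)) {
    abort(paste0("Feature columns mismatch. Missing: ",
                 paste(missing, collapse = ", "), ". Extra: ",
                 paste(extra, collapse = ", "), "."))
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  probs <- matrix(0, nrow(newdata), length(object$class_order),
                  dimnames = list(rownames(newdata), object$class_order))
  for (nm in names(object$bag$learners)) {
    lr <- object$bag$learners[[nm]]
    if (object$weights[[nm]] == 0) next
    impl <- .learner_registry[[lr$name]]
    fold_mean <- Reduce(`+`, lapply(lr$models, impl$predict,
                                    x = newdata)) / object$bag$k
    probs <- probs + object$weights[[nm]] * fold_mean
  }
  ord <- t(apply(probs, 1L, order, decreasing = TRUE))
  out <- tibble(
    sample_id = rownames(newdata) %||% as.character(seq_len(nrow(newdata))),
    predicted = .argmax_label(probs, object$class_order),
    runner_up = object$class_order[ord[, 2L]],
    predicted_prob = probs[cbind(seq_len(nrow(probs)), ord[, 1L])],
    runner_up_prob = probs[cbind(seq_len(nrow(probs)), ord[, 2L])]
  )
  pc <- as_tibble(probs)
  names(pc) <- paste0("prob_", names(pc))
  dplyr::bind_cols(out, pc)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ensemble: one row per base learner
#'
#' @param x An `"ms_ensemble"`.
#' @param ... Ignored.
#' @return Tibble: `learner`, `weight`, `oof_accuracy`.
#' @method tidy ms_ensemble
#' @export
tidy.ms_ensemble <- function(x, ...) {
  tibble(learner = names(x$weights),
         weight = as.numeric(x$weights),
         oof_accuracy = as.numeric(x$learner_oof_accuracy))
}

#' One-row ensemble summary
#'
#' @param x An `"ms_ensemble"`.
#' @param ... Ignored.
#' @return Tibble: `oof_accuracy`, `n_learners`, `k_folds`.
#' @method glance ms_ensemble
#' @export
glance.ms_ensemble <- function(x, ...) {
  tibble(oof_accuracy = x$oof_accuracy,
         n_learners = length(x$weights),
         k_folds = x$bag$k)
}
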