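#' The seven VM reclassification tasks
#'
#' Six pairwise tasks plus the four-way task over the VM types
#' HC, HS, BVC, BVS.
#'
#' @return named list of character vectors of the types each task
#'   discriminates.
#' @export
vm_tasks <- function() {
  list(task1_HC_vs_HS   = c("HC", "HS"),
       task2_BVC_vs_BVS = c("BVC", "BVS"),
       task3_HC_vs_BVC  = c("HC", "BVC"),
       task4_HS_vs_BVS  = c("HS", "BVS"),
       task5_HC_vs_BVS  = c("HC", "BVS"),
       task6_HS_vs_BVC  = c("HS", "BVC"),
       task7_four_way   = c("HC", "HS", "BVC", "BVS"))
}

vm_algorithms <- function() {
  c("logistic_regression", "knn", "random_forest",
    "gradient_boosted_trees", "svm", "dense_neural_net")
}

#' Fit one classifier family
#'
#' Wraps the six classifier families behind one interface. Hyperparameters
#' follow the harness defaults: KNN with 17 neighbors, SVM with the
#' radial-basis C-classifier at cost 1, random forest and gradient-boosted
#' trees at their packages' defaults, multinomial logistic regression, and
#' a dense two-hidden-layer neural network (64/32 units, initial learning
#' rate 0.01, tenfold rate reduction after 30 stalled epochs).
#'
#' @param x numeric feature matrix (samples x features).
#' @param y factor (or coercible) of class labels, one per row of `x`.
#' @param algorithm one of [vm_algorithms()].
#' @param seed integer seed for the stochastic learners.
#' @return a classifier bundle of class `vm4_model` with a [predict()]
#'   method.
#' @export
fit_classifier <- function(x, y, algorithm = vm_algorithms(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x); storage.mode(x) <- "double"
  colnames(x) <- make.names(colnames(x), unique = TRUE)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes to fit a classifier")
  set.seed(as.integer(seed))
  fit <- switch(algorithm,
    logistic_regression = {
      df <- data.frame(x, .y = y, check.names = FALSE)
      nnet::multinom(.y ~ ., data = df, trace = FALSE,
                     maxit = 300L, MaxNWts = 100000L)
    },
    knn = list(train_x = x, train_y = y, k = 17L),
    random_forest = randomForest::randomForest(x, y),
    gradient_boosted_trees =
      xgboost::xgboost(x, y, nrounds = 50L, verbosity = 0),
    svm = e1071::svm(x, y, kernel = "radial", cost = 1),
    dense_neural_net = mlp_train(x, y, seed = seed))
  structure(list(algorithm = algorithm, fit = fit, classes = levels(y),
                 features = colnames(x)),
            class = "vm4_model")
}

#' @export
predict.vm4_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata); storage.mode(x) <- "double"
  colnames(x) <- make.names(colnames(x), unique = TRUE)
  if (!identical(colnames(x), object$features)) {
    miss <- setdiff(object$features, colnames(x))
    extra <- setdiff(colnames(x), object$features)
    if (length(miss) || length(extra)) {
      # align by feature name with zero fill (OTU view across cohorts)
      z <- matrix(0, nrow(x), length(object$features),
                  dimnames = list(rownames(x), object$features))
      common <- intersect(colnames(x), object$features)
      if (length(common) == 0L) stop("no features shared with the model")
      z[, common] <- x[, common]
      x <- z
    }
  }
  cls <- object$classes
  pred <- switch(object$algorithm,
    logistic_regression =
      as.character(stats::predict(object$fit,
                                  newdata = data.frame(x, check.names = FALSE))),
    knn = as.character(class::knn(object$fit$train_x, x, object$fit$train_y,
                                  k = object$fit$k)),
    random_forest = as.character(stats::predict(object$fit, x)),
    gradient_boosted_trees = {
      pr <- stats::predict(object$fit, x)
      if (is.matrix(pr)) colnames(pr)[max.col(pr, ties.method = "first")]
      else cls[(pr > 0.5) + 1L]   # probability of the second class level
    },
    svm = as.character(stats::predict(object$fit, x)),
    dense_neural_net = as.character(stats::predict(object$fit, x)))
  factor(pred, levels = cls)
}

# stratified train-index sampling at the given split fraction
stratified_split <- function(y, split, rng_unused = NULL) {
  unlist(lapply(split(seq_along(y), y), function(idx) {
    n_tr <- max(1L, round(length(idx) * split))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
    sample(idx, n_tr)
  }), use.names = FALSE)
}

#' Run one reclassification task
#'
#' Repeatedly splits the task's samples into stratified 75/25
#' train/test folds, trains the requested classifier on the training fold
#' only, and records the held-out precision (the fraction of test samples
#' whose predicted VM type matches the assigned type).
#'
#' @param features numeric matrix (samples x features): either the
#'   10-metric view or a relative-abundance OTU view (see
#'   [ml_feature_views()]).
#' @param labels factor/character of VM types, one per sample.
#' @param task a task name or index into [vm_tasks()], or a character
#'   vector of types to discriminate.
#' @param algorithm one of [vm_algorithms()].
#' @param n_repeats number of random splits (default 100).
#' @param split training fraction (default 0.75).
#' @param seed integer seed; repeat r uses `seed + r` so the split
#'   sequence is reproducible.
#' @return list of class `vm4_eval` with per-repeat `precision`,
#'   `mean`/`min`/`max`, and the task/algorithm metadata.
#' @export
run_task <- function(features, labels, task = 7L,
                     algorithm = vm_algorithms(), n_repeats = 100L,
                     split = 0.75, seed = 1L) {
  algorithm <- match.arg(algorithm)
  tasks <- vm_tasks()
  types <- if (is.character(task) && length(task) > 1L) task
           else if (is.character(task)) tasks[[task]]
           else tasks[[as.integer(task)]]
  if (is.null(types)) stop("unknown task")
  labels <- as.factor(labels)
  sel <- labels %in% types
  x <- as.matrix(features)[sel, , drop = FALSE]
  y <- factor(as.character(labels[sel]), levels = types)
  n_class <- table(y)
  if (any(n_class < 20L))
    stop("each class needs at least 20 samples; got: ",
         paste(sprintf("%s=%d", names(n_class), n_class), collapse = ", "))
  precision <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(as.integer(seed) + r)
    tr <- stratified_split(y, split)
    model <- fit_classifier(x[tr, , drop = FALSE], y[tr], algorithm,
                            seed = as.integer(seed) + r)
    pred <- predict(model, x[-tr, , drop = FALSE])
    precision[r] <- mean(as.character(pred) == as.character(y[-tr]))
  }
  structure(list(task = types, algorithm = algorithm,
                 precision = precision, mean = mean(precision),
                 min = min(precision), max = max(precision),
                 n_repeats = n_repeats, split = split, seed = seed),
            class = "vm4_eval")
}

#' @export
print.vm4_eval <- function(x, ...) {
  cat(sprintf("%s on %s: mean precision %.3f (min %.3f, max %.3f; %d repeats)\n",
              x$algorithm, paste(x$task, collapse = "/"), x$mean, x$min,
              x$max, x$n_repeats))
  invisible(x)
}

#' Evaluate a trained classifier on an external cohort
#'
#' No refitting: the model predicts the external samples and a single
#' precision value is returned. For OTU-view features the columns are
#' aligned by taxon name, with taxa unseen in training zero-filled.
#'
#' @param model a `vm4_model` from [fit_classifier()].
#' @param features external feature matrix (samples x features).
#' @param labels external true labels.
#' @return list of class `vm4_eval` with a single-element `precision`.
#' @export
external_eval <- function(model, features, labels) {
  if (NROW(features) == 0L) stop("empty external set")
  labels <- as.character(labels)
  if (NROW(features) != length(labels))
    stop("features and labels differ in length")
  pred <- predict(model, features)
  prec <- mean(as.character(pred) == labels)
  structure(list(task = model$classes, algorithm = model$algorithm,
                 precision = prec, mean = prec, min = prec, max = prec,
                 n_repeats = 1L, external = TRUE),
            class = "vm4_eval")
}

#' Build the two feature views for the ML harness
#'
#' @param otu an [otu_table()].
#' @param metrics optional precomputed [compute_metrics()] table.
#' @return list with `otu` (samples x taxa relative abundances) and
#'   `metric10` (samples x 10 metrics) matrices, rows named by sample.
#' @export
ml_feature_views <- function(otu, metrics = NULL) {
  if (is.null(metrics)) metrics <- compute_metrics(otu)
  m10 <- as.matrix(metrics[, metric10_names()])
  rownames(m10) <- metrics$sample_id
  list(otu = t(relative_abundance(otu)), metric10 = m10)
}
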