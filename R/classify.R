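## Classifier families (SVM, distance-weighted k-NN, decision-tree
## ensembles), stratified splitting, evaluation, feature-importance
## progression, and the time-resolved live/apoptotic/necrotic fractions.

RESERVED_COLS <- c("cell_id", "image_id", "label", "line", "state",
                   "line_label", "state_label", "time_min",
                   "degenerate_phase")

feature_columns <- function(samples, feature_names = NULL) {
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, names(samples))
    if (length(missing)) stop("missing feature columns: ",
                              paste(missing, collapse = ", "))
    return(feature_names)
  }
  num <- names(samples)[vapply(samples, is.numeric, logical(1))]
  setdiff(num, RESERVED_COLS)
}

task_labels <- function(samples, task) {
  line <- samples[["line"]] %||% samples[["line_label"]]
  state <- samples[["state"]] %||% samples[["state_label"]]
  switch(task,
         lines = factor(line),
         states = factor(state),
         `9class` = factor(paste(line, state, sep = "/")),
         stop("unknown task '", task,
              "'; expected 'lines', 'states' or '9class'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified train/test split
#'
#' Splits a labelled sample table into disjoint train and test sets,
#' stratified by the joint (line, state) label, reproducibly under a seed.
#'
#' @param samples Tibble with `line` and `state` columns (or `line_label` /
#'   `state_label`) and feature columns.
#' @param test_fraction Fraction of each class held out for testing.
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (tibbles).
#' @export
split_train_test <- function(samples, test_fraction = 0.2, seed = 1) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  strata <- as.character(task_labels(samples, "9class"))
  tab <- table(strata)
  if (any(tab < 2)) {
    stop("every class needs at least 2 samples to split; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(samples)), strata), function(idx) {
      n_test <- max(1L, round(length(idx) * test_fraction))
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  list(train = samples[-test_idx, ], test = samples[test_idx, ])
}

#' Classifier specification
#'
#' @param family `"svm"`, `"knn"` or `"ec"` (ensemble classifier).
#' @param svm_kernel `"linear"`, `"quadratic"`, `"cubic"` or `"gaussian"`;
#'   quadratic/cubic are polynomial kernels of degree 2/3 with `coef0 = 1`.
#' @param svm_cost SVM regularisation constant C.
#' @param knn_metric `"cosine"` or `"cubic"` (Minkowski p = 3).
#' @param knn_weighting `"uniform"` or `"distance"` (votes weighted 1/d).
#' @param knn_k Number of neighbours.
#' @param ec_method `"random_forest"` (Breiman) or `"adaboost"` (SAMME on
#'   shallow decision trees).
#' @param ec_ntree Trees in the forest / boosting rounds.
#' @param standardize Z-score features on training statistics.
#' @param seed Seed used when fitting has a stochastic component.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "knn", "ec"),
                            svm_kernel = c("quadratic", "linear", "cubic",
                                           "gaussian"),
                            svm_cost = 1,
                            knn_metric = c("cosine", "cubic"),
                            knn_weighting = c("distance", "uniform"),
                            knn_k = 7,
                            ec_method = c("random_forest", "adaboost"),
                            ec_ntree = 200,
                            standardize = TRUE, seed = 1) {
  structure(
    list(family = match.arg(family), svm_kernel = match.arg(svm_kernel),
         svm_cost = svm_cost, knn_metric = match.arg(knn_metric),
         knn_weighting = match.arg(knn_weighting), knn_k = as.integer(knn_k),
         ec_method = match.arg(ec_method), ec_ntree = as.integer(ec_ntree),
         standardize = isTRUE(standardize), seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

#' Train a cell classifier
#'
#' Fits the classifier family named by `spec` on the feature columns of
#' `train`: a support vector machine (one-vs-one multiclass, polynomial
#' degree 2/3 for the quadratic/cubic kernels), a distance-weighted k-nearest
#' neighbour rule (cosine or Minkowski p = 3 metric), or a decision-tree
#' ensemble (Breiman random forest or SAMME AdaBoost). Features are z-scored
#' on training statistics when `spec$standardize` is set; zero-variance
#' features are dropped with a warning.
#'
#' @param train Training samples (tibble with label and feature columns).
#' @param spec A [classifier_spec()].
#' @param task `"lines"`, `"states"` or `"9class"`.
#' @param feature_names Optional explicit feature subset.
#' @return Object of class `trained_classifier`.
#' @export
train_classifier <- function(train, spec = classifier_spec(),
                             task = "9class", feature_names = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), nrow(train) > 0)
  feats <- feature_columns(train, feature_names)
  y <- droplevels(task_labels(train, task))
  X <- as.matrix(train[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  keep <- apply(X, 2, stats::sd) > 1e-12
  if (any(!keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(feats[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    feats <- feats[keep]
  }
  if (!length(feats)) stop("no usable features")
  if (spec$standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    X <- sweep(sweep(X, 2, center), 2, scale, "/")
  } else {
    center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  }
  fit <- with_seed(spec$seed, switch(
    spec$family,
    svm = {
      kern <- switch(spec$svm_kernel,
                     linear = list(kernel = "linear", degree = 3),
                     quadratic = list(kernel = "polynomial", degree = 2),
                     cubic = list(kernel = "polynomial", degree = 3),
                     gaussian = list(kernel = "radial", degree = 3))
      e1071::svm(X, y, kernel = kern$kernel, degree = kern$degree,
                 coef0 = if (kern$kernel == "polynomial") 1 else 0,
                 cost = spec$svm_cost, scale = FALSE)
    },
    knn = list(X = X, y = y),
    ec = if (spec$ec_method == "random_forest") {
      randomForest::randomForest(X, y, ntree = spec$ec_ntree)
    } else {
      fit_adaboost(X, y, n_rounds = min(spec$ec_ntree, 100L))
    }
  ))
  structure(
    list(spec = spec, task = task, fit = fit, feature_names = feats,
         center = center, scale = scale, levels = levels(y),
         n_per_class = table(y)),
    class = "trained_classifier"
  )
}

## SAMME multiclass AdaBoost on shallow rpart trees
fit_adaboost <- function(X, y, n_rounds = 60, maxdepth = 3) {
  n <- nrow(X); K <- nlevels(y)
  w <- rep(1 / n, n)
  df <- data.frame(y = y, X)
  trees <- list(); alphas <- numeric()
  for (m in seq_len(n_rounds)) {
    tr <- rpart::rpart(y ~ ., data = df, weights = w,
                       control = rpart::rpart.control(maxdepth = maxdepth,
                                                      cp = 0, xval = 0,
                                                      minsplit = 4))
    pred <- stats::predict(tr, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    trees[[length(trees) + 1]] <- tr
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err < 1e-8) break
  }
  structure(list(trees = trees, alphas = alphas, levels = levels(y)),
            class = "adaboost_fit")
}

predict_adaboost <- function(object, X) {
  scores <- matrix(0, nrow(X), length(object$levels),
                   dimnames = list(NULL, object$levels))
  df <- data.frame(X)
  for (m in seq_along(object$trees)) {
    pred <- stats::predict(object$trees[[m]], df, type = "class")
    scores[cbind(seq_len(nrow(X)), as.integer(pred))] <-
      scores[cbind(seq_len(nrow(X)), as.integer(pred))] + object$alphas[m]
  }
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

predict_knn <- function(train_X, train_y, X, k, metric, weighting) {
  if (metric == "cosine") {
    nt <- sqrt(rowSums(train_X^2)); nq <- sqrt(rowSums(X^2))
    sim <- (X %*% t(train_X)) / (pmax(nq, 1e-12) %o% pmax(nt, 1e-12))
    D <- 1 - sim
  } else {                                       # Minkowski p = 3
    D <- matrix(0, nrow(X), nrow(train_X))
    for (j in seq_len(ncol(X))) {
      D <- D + abs(outer(X[, j], train_X[, j], "-"))^3
    }
    D <- D^(1 / 3)
  }
  lv <- levels(train_y)
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    ord <- order(D[i, ])[seq_len(min(k, ncol(D)))]
    wts <- if (weighting == "distance") 1 / (D[i, ord] + 1e-9) else
      rep(1, length(ord))
    votes <- tapply(wts, train_y[ord], sum, default = 0)
    out[i] <- names(votes)[which.max(votes)]
  }
  factor(out, levels = lv)
}

#' Predict with a trained classifier
#'
#' @param object A [train_classifier()] fit.
#' @param newdata Tibble containing the training feature columns.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing)) {
    stop("newdata lacks feature column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  pred <- switch(
    object$spec$family,
    svm = stats::predict(object$fit, X),
    knn = predict_knn(object$fit$X, object$fit$y, X, object$spec$knn_k,
                      object$spec$knn_metric, object$spec$knn_weighting),
    ec = if (inherits(object$fit, "adaboost_fit")) {
      predict_adaboost(object$fit, X)
    } else {
      stats::predict(object$fit, X)
    })
  factor(as.character(pred), levels = object$levels)
}

#' @export
print.trained_classifier <- function(x, ...) {
  opt <- switch(x$spec$family,
                svm = paste0("kernel=", x$spec$svm_kernel),
                knn = paste0("k=", x$spec$knn_k, ", metric=", x$spec$knn_metric,
                             ", weighting=", x$spec$knn_weighting),
                ec = x$spec$ec_method)
  cat(sprintf("trained_classifier: %s (%s), task=%s, %d features, %d classes\n",
              x$spec$family, opt, x$task, length(x$feature_names),
              length(x$levels)))
  invisible(x)
}

#' Evaluate a classifier on held-out samples
#'
#' @param model A [train_classifier()] fit.
#' @param test Test samples carrying the same label and feature columns.
#' @return Object of class `evaluation_report`: accuracy (%), confusion
#'   matrix (true x predicted counts), per-class recall, task name.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "trained_classifier"), nrow(test) > 0)
  truth <- factor(as.character(task_labels(test, model$task)),
                  levels = model$levels)
  pred <- stats::predict(model, test)
  cm <- table(true = truth, predicted = pred)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  structure(
    list(accuracy_pct = acc, confusion = cm, per_class_recall = recall,
         task = model$task, n_test = nrow(test), spec = model$spec),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: task=%s, accuracy %.1f%% on %d cells\n",
              x$task, x$accuracy_pct, x$n_test))
  print(x$confusion)
  invisible(x)
}

#' Classification accuracy over nested feature subsets
#'
#' Trains and evaluates on nested prefixes of a feature ranking (1, 2, ...
#' features) on a fixed stratified split. When no ranking is supplied, a
#' greedy forward ranking is computed first (each step adds the feature with
#' the largest test-accuracy gain).
#'
#' @param samples Labelled feature table.
#' @param spec A [classifier_spec()].
#' @param ranking Ordered character vector of feature names, or `NULL`.
#' @param task Classification task (see [train_classifier()]).
#' @param test_fraction,seed Split parameters.
#' @return Tibble with `n_features`, `feature_added`, `accuracy_pct`; the
#'   ranking used is attached as attribute `ranking`.
#' @export
feature_subset_analysis <- function(samples, spec = classifier_spec(),
                                    ranking = NULL, task = "9class",
                                    test_fraction = 0.2, seed = 1) {
  if (!is.null(ranking) && length(ranking) == 0) {
    stop("empty feature ranking")
  }
  all_feats <- feature_columns(samples)
  if (!is.null(ranking)) {
    missing <- setdiff(ranking, all_feats)
    if (length(missing)) stop("ranking names unknown features: ",
                              paste(missing, collapse = ", "))
  }
  sp <- split_train_test(samples, test_fraction, seed)
  acc_of <- function(feats) {
    m <- train_classifier(sp$train, spec, task, feature_names = feats)
    evaluate(m, sp$test)$accuracy_pct
  }
  if (is.null(ranking)) {
    remaining <- all_feats; ranking <- character()
    while (length(remaining)) {
      accs <- vapply(remaining, function(f) acc_of(c(ranking, f)), numeric(1))
      best <- remaining[which.max(accs)]
      ranking <- c(ranking, best)
      remaining <- setdiff(remaining, best)
    }
  }
  acc <- vapply(seq_along(ranking),
                function(d) acc_of(ranking[seq_len(d)]), numeric(1))
  out <- tibble::tibble(n_features = seq_along(ranking),
                        feature_added = ranking, accuracy_pct = acc)
  attr(out, "ranking") <- ranking
  class(out) <- c("feature_subset_curve", class(out))
  out
}

#' Time-resolved fractions of live, apoptotic and necrotic cells
#'
#' For every frame of a monitoring series: segment, extract the QPI feature
#' vector of each cell, predict its state, and report per-timepoint counts
#' and fractions.
#'
#' @param frames Tibble with columns `time_min` and `phase` (list of
#'   [phase_image()]), e.g. from [simulate_treatment_series()].
#' @param model A [train_classifier()] fit with `task = "states"`.
#' @param segment_config A [segmentation_config()].
#' @param constants [optical_constants()].
#' @param dose_mw_cm2 Optional treatment dose recorded with the result.
#' @return Object of class `timeseries_fractions`: tibble with `time_min`,
#'   `n_cells`, counts and `frac_live`, `frac_apoptotic`, `frac_necrotic`
#'   (NA when a frame contains no cells).
#' @export
classify_time_series <- function(frames, model,
                                 segment_config = segmentation_config(),
                                 constants = optical_constants(),
                                 dose_mw_cm2 = NA_real_) {
  stopifnot(inherits(model, "trained_classifier"))
  if (model$task != "states") {
    stop("time-series classification needs a model trained on task = 'states'")
  }
  rows <- vector("list", nrow(frames))
  for (t in seq_len(nrow(frames))) {
    phase <- frames$phase[[t]]
    seg <- suppressWarnings(segment_cells(phase, segment_config))
    feats <- extract_features(phase, seg, constants,
                              image_id = paste0("t", frames$time_min[t]))
    if (nrow(feats) == 0) {
      rows[[t]] <- tibble::tibble(
        time_min = frames$time_min[t], n_cells = 0L,
        n_live = 0L, n_apoptotic = 0L, n_necrotic = 0L,
        frac_live = NA_real_, frac_apoptotic = NA_real_,
        frac_necrotic = NA_real_)
      next
    }
    pred <- stats::predict(model, feats)
    counts <- table(factor(as.character(pred),
                           levels = c("live", "apoptotic", "necrotic")))
    n <- sum(counts)
    rows[[t]] <- tibble::tibble(
      time_min = frames$time_min[t], n_cells = n,
      n_live = as.integer(counts["live"]),
      n_apoptotic = as.integer(counts["apoptotic"]),
      n_necrotic = as.integer(counts["necrotic"]),
      frac_live = counts[["live"]] / n,
      frac_apoptotic = counts[["apoptotic"]] / n,
      frac_necrotic = counts[["necrotic"]] / n)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "dose_mw_cm2") <- dose_mw_cm2
  class(out) <- c("timeseries_fractions", class(out))
  out
}
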