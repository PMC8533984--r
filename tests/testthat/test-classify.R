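test_that("stratified splitting is balanced, disjoint and reproducible", {
  blobs <- make_blobs(100, d = 3)
  sp <- split_train_test(blobs, 0.2, seed = 5)
  expect_equal(nrow(sp$train), 240)
  expect_equal(nrow(sp$test), 60)
  expect_true(all(table(sp$test$state) == 20))
  sp2 <- split_train_test(blobs, 0.2, seed = 5)
  expect_identical(sp$test, sp2$test)
  expect_error(split_train_test(blobs, 0), "between 0 and 1")
  one <- blobs[c(1, 101, 201, 2), ]
  expect_error(split_train_test(one, 0.2), "at least 2")
})

test_that("all classifier families separate well-separated blobs", {
  blobs <- make_blobs(70, d = 10, sep = 10, seed = 2)
  sp <- split_train_test(blobs, 0.2, seed = 3)
  for (fam in c("svm", "knn", "ec")) {
    m <- train_classifier(sp$train, classifier_spec(fam), task = "states")
    expect_equal(evaluate(m, sp$train)$accuracy_pct, 100)
    expect_equal(evaluate(m, sp$test)$accuracy_pct, 100)
  }
  # both ensemble variants and both knn metrics work
  for (spec in list(classifier_spec("ec", ec_method = "adaboost",
                                    ec_ntree = 30),
                    classifier_spec("knn", knn_metric = "cubic"),
                    classifier_spec("svm", svm_kernel = "gaussian"))) {
    m <- train_classifier(sp$train, spec, task = "states")
    expect_gte(evaluate(m, sp$test)$accuracy_pct, 95)
  }
})

test_that("label permutation drops accuracy to chance level", {
  blobs <- make_blobs(40, d = 6, sep = 8, seed = 4)
  accs <- vapply(1:10, function(s) {
    set.seed(s + 50)
    perm <- blobs
    perm$state <- sample(perm$state)
    sp <- split_train_test(perm, 0.2, seed = s)
    m <- train_classifier(sp$train, classifier_spec("svm"), task = "states")
    evaluate(m, sp$test)$accuracy_pct
  }, numeric(1))
  n_test <- 24
  binom_sd <- 100 * sqrt((1 / 3) * (2 / 3) / n_test)
  expect_lt(abs(mean(accs) - 100 / 3), 3 * binom_sd)
})

test_that("evaluation accounting is internally consistent", {
  blobs <- make_blobs(30, d = 4, sep = 9, seed = 6)
  sp <- split_train_test(blobs, 0.2, seed = 1)
  m <- train_classifier(sp$train, classifier_spec("knn"), task = "states")
  ev <- evaluate(m, sp$test)
  expect_equal(sum(ev$confusion), nrow(sp$test))
  expect_equal(ev$accuracy_pct,
               100 * sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.vector(table(factor(sp$test$state,
                                             levels = m$levels)))))
  # unseen feature set is rejected
  bad <- sp$test; names(bad)[names(bad) == "f1"] <- "g1"
  expect_error(predict(m, bad), "lacks feature")
  # tidiers
  expect_equal(sum(tidy(ev)$n), nrow(sp$test))
  expect_equal(glance(ev)$accuracy_pct, ev$accuracy_pct)
  expect_equal(nrow(tidy(m)), length(m$feature_names))
})

test_that("zero-variance features are dropped with a warning", {
  blobs <- make_blobs(20, d = 3, sep = 9, seed = 7)
  blobs$f3 <- 1
  expect_warning(
    m <- train_classifier(blobs, classifier_spec("svm"), task = "states"),
    "zero-variance")
  expect_false("f3" %in% m$feature_names)
})

test_that("nested feature subsets: flat once the signal is exhausted", {
  set.seed(8)
  n <- 240
  df <- tibble::tibble(
    line = "HeLa",
    state = rep(c("live", "apoptotic", "necrotic"), each = n / 3),
    f1 = rep(c(0, 6, 12), each = n / 3) + rnorm(n),
    f2 = rnorm(n), f3 = rnorm(n))
  curve <- feature_subset_analysis(df, classifier_spec("svm"),
                                   ranking = c("f1", "f2", "f3"),
                                   task = "states", seed = 2)
  expect_equal(nrow(curve), 3)
  expect_gte(curve$accuracy_pct[1], 95)
  expect_lt(max(abs(diff(curve$accuracy_pct))), 6)
  expect_error(feature_subset_analysis(df, ranking = character()), "empty")
  expect_error(feature_subset_analysis(df, ranking = c("f1", "nope")),
               "unknown")
})

test_that("greedy forward ranking finds the informative feature first", {
  set.seed(9)
  n <- 180
  df <- tibble::tibble(
    line = "HeLa",
    state = rep(c("live", "apoptotic", "necrotic"), each = n / 3),
    noise_a = rnorm(n),
    signal = rep(c(0, 7, 14), each = n / 3) + rnorm(n),
    noise_b = rnorm(n))
  curve <- feature_subset_analysis(df, classifier_spec("svm"),
                                   task = "states", seed = 3)
  expect_equal(attr(curve, "ranking")[1], "signal")
  # accuracy never drops much as features are added (nestedness, 5 splits)
  for (s in 1:5) {
    cs <- feature_subset_analysis(df, classifier_spec("svm"),
                                  ranking = c("signal", "noise_a", "noise_b"),
                                  task = "states", seed = s)
    expect_true(all(diff(cs$accuracy_pct) > -6))
  }
})

test_that("classifier training is deterministic given data and seed", {
  blobs <- make_blobs(30, d = 5, sep = 6, seed = 10)
  sp <- split_train_test(blobs, 0.2, seed = 4)
  for (fam in c("svm", "ec")) {
    m1 <- train_classifier(sp$train, classifier_spec(fam, seed = 3), "states")
    m2 <- train_classifier(sp$train, classifier_spec(fam, seed = 3), "states")
    expect_identical(predict(m1, sp$test), predict(m2, sp$test))
  }
})

test_that("time-series classification reports coherent fractions", {
  ds <- small_dataset()
  feats <- dataset_features(ds)
  m <- train_classifier(feats, classifier_spec("svm"), task = "states")
  frames <- simulate_treatment_series(n_timepoints = 2, n_cells = 4,
                                      seed = 3, noise = FALSE)
  ts <- classify_time_series(frames, m)
  expect_equal(nrow(ts), 2)
  ok <- !is.na(ts$frac_live)
  expect_true(all(abs(ts$frac_live + ts$frac_apoptotic +
                        ts$frac_necrotic - 1)[ok] < 1e-9))
  expect_equal(ts$n_live + ts$n_apoptotic + ts$n_necrotic, ts$n_cells)
  # an empty frame yields missing fractions
  empty <- tibble::tibble(time_min = 0,
                          phase = list(phase_image(matrix(0, 64, 64), 0.5)))
  ts0 <- suppressWarnings(classify_time_series(empty, m))
  expect_true(is.na(ts0$frac_live))
  expect_equal(ts0$n_cells, 0L)
  # a lines model is refused
  ml <- train_classifier(feats, classifier_spec("svm"), task = "lines")
  expect_error(classify_time_series(frames, ml), "states")
})
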