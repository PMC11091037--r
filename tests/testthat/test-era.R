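test_that("quadrant labeling follows the 1-4 / 6-9 binary splits", {
  expect_equal(quadrant_label(7, 3), "LAHV")  # relaxed
  expect_equal(quadrant_label(3, 3), "LALV")  # sad
  expect_equal(quadrant_label(7, 8), "HAHV")
  expect_equal(quadrant_label(2, 7), "HALV")
  expect_equal(quadrant_label(5, 2), "excluded")
  expect_equal(quadrant_label(7, 4.5), "excluded")
  expect_equal(quadrant_label(4, 6), "HALV")  # boundary values count
  expect_equal(quadrant_label(c(7, 3), c(3, 3)), c("LAHV", "LALV"))
  expect_error(quadrant_label(10, 3), "\\[1, 9\\]")
  expect_error(quadrant_label(5, 0.5), "\\[1, 9\\]")
})

test_that("accuracy is percent correct", {
  expect_equal(accuracy(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 1),
                        c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)), 90)
  expect_equal(accuracy(letters[1:5], letters[1:5]), 100)
  expect_error(accuracy(character(0), character(0)), "empty")
  expect_error(accuracy(1:3, 1:4), "length")
  # permutation null on balanced data sits near 50%
  set.seed(51)
  y <- rep(c("a", "b"), 5000)
  expect_lt(abs(accuracy(sample(y), y) - 50), 3)
})

test_that("k-fold evaluation separates blobs and is honest on null data", {
  set.seed(52)
  n <- 200
  y <- rep(c("a", "b"), each = n / 2)
  X <- rbind(matrix(rnorm(n, 0, 0.5), n / 2),
             matrix(rnorm(n, 3, 0.5), n / 2))
  cv <- kfold_evaluate(X, y, classifier = "knn", k_folds = 5, seed = 1,
                       pca = NULL)
  expect_gte(cv$mean_accuracy, 95)
  expect_length(cv$fold_accuracies, 5)

  set.seed(53)
  Xn <- matrix(rnorm(400 * 4), 400)
  yn <- sample(rep(c("a", "b"), 200))
  cvn <- kfold_evaluate(Xn, yn, classifier = "knn", k_folds = 5, seed = 1,
                        pca = NULL)
  expect_gte(cvn$mean_accuracy, 40)
  expect_lte(cvn$mean_accuracy, 60)
})

test_that("all three classifiers run behind the same contract", {
  set.seed(54)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  X <- rbind(matrix(rnorm(2 * n / 2, 0, 0.6), n / 2),
             matrix(rnorm(2 * n / 2, 2.5, 0.6), n / 2))
  for (clf in c("knn", "svm", "gboost")) {
    cv <- kfold_evaluate(X, y, classifier = clf, k_folds = 5, seed = 2,
                         pca = NULL)
    expect_gte(cv$mean_accuracy, 85)
    expect_length(cv$predictions, n)
  }
  expect_error(kfold_evaluate(X, rep("a", n), "knn", pca = NULL),
               "both classes")
  expect_error(kfold_evaluate(X, y, "forest", pca = NULL), "unknown classifier")
})

test_that("leave-one-out returns one fold value per observation", {
  set.seed(55)
  n <- 12
  y <- rep(c("a", "b"), each = 6)
  X <- cbind(rnorm(n, ifelse(y == "a", 0, 3)), rnorm(n))
  cv <- kfold_evaluate(X, y, classifier = "knn", k_folds = n, seed = 3,
                       pca = NULL)
  expect_length(cv$fold_accuracies, n)
  expect_true(all(cv$fold_accuracies %in% c(0, 100)))
})

test_that("evaluation is reproducible under a fixed seed", {
  set.seed(56)
  X <- matrix(rnorm(80 * 6), 80)
  y <- rep(c("a", "b"), 40)
  for (clf in c("knn", "svm", "gboost")) {
    cv1 <- kfold_evaluate(X, y, classifier = clf, seed = 9)
    cv2 <- kfold_evaluate(X, y, classifier = clf, seed = 9)
    expect_identical(cv1$predictions, cv2$predictions)
    expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)
  }
})

test_that("group-level folds keep all windows of a trial together", {
  set.seed(57)
  n_trial <- 20
  rows_per <- 5
  groups <- rep(sprintf("T%02d", 1:n_trial), each = rows_per)
  y <- rep(rep(c("a", "b"), n_trial / 2), each = rows_per)
  X <- matrix(rnorm(n_trial * rows_per * 4), ncol = 4)
  cv <- kfold_evaluate(X, y, classifier = "knn", k_folds = 5, seed = 4,
                       groups = groups, pca = NULL)
  expect_true(all(tapply(cv$fold, groups, function(f) length(unique(f))) == 1))
})

test_that("run_era recovers an injected late high-alpha effect", {
  rs <- generate_dataset(synth_config(n_trials_per_class = 10, seed = 101))
  ec <- era_config(subbands = c("high_alpha", "low_alpha"), n_groups = 4,
                   window = window_spec(3, 2), seed = 7)
  res <- run_era(rs, ec)
  expect_equal(res$best$sub_band, "high_alpha")
  expect_equal(res$best$period_group, 4)
  expect_gte(res$best$window_index, 2)
  # invariants: best accuracy is the grid max; objective the cell min
  expect_equal(res$best$accuracy, max(res$grid$accuracy))
  cell <- res$objectives[res$objectives$sub_band == res$best$sub_band &
                         res$objectives$period_group == res$best$period_group &
                         res$objectives$selectable, ]
  expect_equal(res$best$objective, min(cell$errors))
  expect_false(any(res$objectives$window_index[res$objectives$selectable] < 2))
  # accuracy consistent with the squared-error objective on binary labels
  expect_equal(nrow(res$grid), 8)
})

test_that("a single period group is trivially selected", {
  rs <- small_synth_set(4, seed = 102)
  ec <- era_config(subbands = "high_alpha", n_groups = 1,
                   window = window_spec(3, 3), seed = 8)
  res <- run_era(rs, ec)
  expect_equal(res$best$period_group, 1)
})

test_that("stronger class separation never hurts best accuracy", {
  accs <- vapply(c(10, 20, 30), function(boost) {
    rs <- generate_dataset(synth_config(
      n_trials_per_class = 10, seed = 103,
      relaxed = list(low_alpha_amp = 10, high_alpha_amp = boost,
                     onset_s = 45)))
    run_era(rs, fast_era_config())$best$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})

test_that("excluded subjects contribute no trials", {
  rs <- small_synth_set(4, seed = 104)
  for (i in seq_along(rs$recordings))
    rs$recordings[[i]]$subject_id <- if (i <= 2) "S13" else "S01"
  ec <- fast_era_config(exclude_subjects = c("S13", "S20", "S21", "S22"),
                        k_folds = 3)
  res <- run_era(rs, ec)
  expect_equal(res$n_trials, 6)
})

test_that("degenerate inputs raise data and configuration errors", {
  rs <- small_synth_set(2, seed = 105)
  keep <- c(1, 2, 4)  # one relaxed, two sad
  rs2 <- recording_set(rs$recordings[keep], rs$ratings[keep, ])
  expect_error(run_era(rs2, fast_era_config()), "at least 2 trials")
  expect_error(run_era(small_synth_set(3, seed = 106),
                       era_config(subbands = "high_alpha", n_groups = 4,
                                  window = window_spec(16, 2))),
               "exceeds the period-group length")
})
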