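# small separable fixture shared across blocks
separable_features <- function(n_per_class = 30L, seed = 21L) {
  data <- small_labeled_dataset(n_per_class, n_per_class, strength = 1, seed = seed)
  assemble_features(data, encoder_config(), motifs = fixture_motifs())
}

test_that("classifier_spec validates family names and hyperparameters", {
  spec <- classifier_spec("svm")
  expect_equal(spec$svm_c, 0.98)
  expect_equal(spec$svm_gamma, 0.01)
  expect_equal(classifier_spec("extratrees")$n_trees, 1000L)
  expect_error(classifier_spec("deep_net"), "unknown classifier family")
  expect_error(classifier_spec("svm", svm_c = -1), "svm_c")
  expect_error(classifier_spec("extratrees", n_trees = 0), "n_trees")
})

test_that("make_folds stratifies exactly, is deterministic and rejects tiny classes", {
  labels <- rep(c("positive", "negative"), each = 50)
  folds <- make_folds(labels, 5L, seed = 1L)
  expect_setequal(unique(folds), 1:5)
  for (f in 1:5) {
    expect_equal(sum(folds == f & labels == "positive"), 10L)
    expect_equal(sum(folds == f & labels == "negative"), 10L)
  }
  expect_identical(make_folds(labels, 5L, seed = 1L), folds)
  expect_false(identical(make_folds(labels, 5L, seed = 2L), folds))
  expect_error(
    make_folds(rep(c("positive", "negative"), c(3, 20)), 5L),
    "fewer than n_folds"
  )
})

test_that("unbalanced classes give per-class fold sizes differing by at most one", {
  labels <- rep(c("positive", "negative"), c(23, 31))
  folds <- make_folds(labels, 5L, seed = 3L)
  for (cls in c("positive", "negative")) {
    sizes <- table(folds[labels == cls])
    expect_lte(max(sizes) - min(sizes), 1L)
  }
})

test_that("fitting memorizes a separable training set and refits reproducibly", {
  fm <- separable_features(15L)
  spec <- classifier_spec("extratrees", n_trees = 100L, seed = 5L)
  model <- fit_classifier(fm, spec)
  scores <- predict_scores(model, fm)
  expect_true(all(scores >= 0 & scores <= 1))
  pm <- point_metrics(confusion_counts(
    as.character(fm$labels), ifelse(scores >= 0.5, "positive", "negative")
  ))
  expect_equal(pm$acc, 1)
  model2 <- fit_classifier(fm, spec)
  expect_identical(predict_scores(model2, fm), scores)

  one_class <- fm_subset(fm, as.character(fm$labels) == "positive")
  expect_error(fit_classifier(one_class, spec), "single class")
})

test_that("every family trains, scores in [0,1] and beats chance on separable data", {
  fm <- separable_features(20L)
  for (family in c("extratrees", "random_forest", "gradient_boosting", "adaboost", "svm")) {
    spec <- classifier_spec(family, n_trees = 50L, seed = 2L)
    model <- fit_classifier(fm, spec)
    scores <- predict_scores(model, fm)
    expect_true(all(scores >= 0 & scores <= 1), info = family)
    expect_gt(roc_auc(as.character(fm$labels), scores)$auc, 0.9)
  }
})

test_that("prediction rejects renamed or reordered feature columns loudly", {
  fm <- separable_features(10L)
  model <- fit_classifier(fm, classifier_spec("extratrees", n_trees = 50L))
  reordered <- fm
  perm <- rev(seq_along(fm$feature_names))
  reordered$feature_names <- fm$feature_names[perm]
  reordered$x <- fm$x[, perm, drop = FALSE]
  expect_error(predict_scores(model, reordered), "feature mismatch at column 1")
  shrunk <- fm
  shrunk$feature_names <- fm$feature_names[-1]
  shrunk$x <- fm$x[, -1, drop = FALSE]
  expect_error(predict_scores(model, shrunk), "expects 461 features")
})

test_that("cross-validation means equal independently recomputed per-fold means", {
  fm <- separable_features(15L)
  folds <- make_folds(as.character(fm$labels), 5L, seed = 1L)
  cv <- cross_validate(fm, classifier_spec("extratrees", n_trees = 50L), folds)
  expect_length(cv$per_fold, 5L)
  for (field in c("sn", "sp", "acc", "mcc", "auc", "ap", "f1")) {
    expect_equal(
      cv$mean[[field]],
      mean(vapply(cv$per_fold, function(r) r[[field]], numeric(1))),
      tolerance = 1e-15
    )
  }
  expect_identical(cv$fold_assignment, folds)
  expect_equal(cv$mean$auc, 1)
})

test_that("fold assignments are reusable across families without mutation", {
  fm <- separable_features(12L)
  folds <- make_folds(as.character(fm$labels), 4L, seed = 9L)
  snapshot <- folds
  cv_a <- cross_validate(fm, classifier_spec("extratrees", n_trees = 40L), folds)
  cv_b <- cross_validate(fm, classifier_spec("svm"), folds)
  expect_identical(folds, snapshot)
  expect_identical(cv_a$fold_assignment, cv_b$fold_assignment)
})

test_that("permuted labels drive cross-validated AUC to chance", {
  data <- small_labeled_dataset(200L, 200L, strength = 1, seed = 31L)
  fm <- assemble_features(data, encoder_config(subsets = "binary"))
  permuted <- fm
  permuted$labels <- withr::with_seed(32L, sample(fm$labels))
  folds <- make_folds(as.character(permuted$labels), 5L, seed = 1L)
  cv <- cross_validate(permuted, classifier_spec("extratrees", n_trees = 200L, seed = 1L), folds)
  expect_gt(cv$mean$auc, 0.42)
  expect_lt(cv$mean$auc, 0.58)
})

test_that("cross-validated AUC does not degrade as the planted motif strengthens", {
  aucs <- vapply(c(0, 0.5, 1), function(strength) {
    data <- generate_dataset(synthetic_spec(
      n_pos = 100L, n_neg = 100L, motif_strength = strength,
      center_A = FALSE, seed = 33L
    ))
    fm <- assemble_features(data, encoder_config(), motifs = fixture_motifs(),
      center_policy = "none"
    )
    folds <- make_folds(as.character(fm$labels), 5L, seed = 1L)
    cross_validate(fm, classifier_spec("extratrees", n_trees = 300L, seed = 1L), folds)$mean$auc
  }, numeric(1))
  expect_gt(aucs[2], aucs[1] - 0.05)
  expect_gt(aucs[3], aucs[2] - 0.05)
  expect_gt(aucs[3], 0.95)
})

test_that("SVM grid search is exhaustive with deterministic tie-breaking", {
  fm <- separable_features(10L)
  folds <- make_folds(as.character(fm$labels), 4L, seed = 1L)
  single <- grid_search_svm(fm, folds, c_grid = 0.98, gamma_grid = 0.01)
  expect_equal(single$best_c, 0.98)
  expect_equal(single$best_gamma, 0.01)
  expect_equal(nrow(single$table), 1L)

  gs <- grid_search_svm(fm, folds, c_grid = c(0.5, 1), gamma_grid = c(0.01, 0.1, 1000))
  expect_equal(nrow(gs$table), 6L)
  # a wildly overfitting gamma cannot win against a sensible cell
  expect_lt(gs$best_gamma, 1000)
  # ties break toward smaller C then smaller gamma
  tied <- gs$table
  tied$mean_auc <- 1
  best_row <- tied[order(-tied$mean_auc, tied$c, tied$gamma), ][1, ]
  expect_equal(best_row$c, 0.5)
  expect_equal(best_row$gamma, 0.01)
})

test_that("jackknife pools one leave-one-out prediction per sample, deterministically", {
  fm <- separable_features(12L) # n = 24
  spec <- classifier_spec("extratrees", n_trees = 100L, seed = 4L)
  rep1 <- jackknife(fm, spec)
  expect_length(attr(rep1, "scores"), 24L)
  expect_equal(rep1$acc, 1)
  rep2 <- jackknife(fm, spec)
  expect_identical(attr(rep2, "scores"), attr(rep1, "scores"))
  expect_error(jackknife(fm_subset(fm, 1:2), spec), "at least 3")
})

test_that("the density+binary SVM baseline preset has the documented shape and runs in CV", {
  data <- small_labeled_dataset(15L, 15L, seed = 22L)
  preset <- baseline_idna6ma_pseknc(data)
  expect_equal(length(preset$features$feature_names), 41L + 123L)
  expect_equal(preset$spec$family, "svm")
  expect_equal(preset$spec$svm_c, 0.336)
  expect_equal(preset$spec$svm_gamma, 0.02)
  folds <- make_folds(as.character(preset$features$labels), 3L, seed = 1L)
  cv <- cross_validate(preset$features, preset$spec, folds)
  expect_length(cv$per_fold, 3L)
  short <- generate_dataset(synthetic_spec(5L, 5L, window_length = 21L, planted_motif = NULL))
  expect_error(baseline_idna6ma_pseknc(short), "41-nt")
})
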