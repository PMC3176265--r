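fast_cfg <- function(seed = 1, folds = 10)
  svm_config(C_grid = 1, gamma_grid = 0.125, cv_folds = folds, seed = seed)

test_that("training is deterministic and separable data fit perfectly", {
  ds <- make_synthetic_dataset(n = 100, prevalence = 0.5, d = 6, seed = 2)
  cfg <- svm_config(C_grid = 2^c(-1, 1, 3), gamma_grid = 2^c(-5, -3),
                    seed = 7)
  m1 <- train_svm(ds, cfg)
  m2 <- train_svm(ds, cfg)
  expect_equal(c(m1$C, m1$gamma), c(m2$C, m2$gamma))
  p <- predict_svm(m1, ds$X)
  expect_equal(p$label, ds$y)
  expect_equal(p$label, p$score >= 0)  # sign rule, ties to positive
  rep <- self_consistency(ds, cfg)
  expect_equal(rep$f1, 1.0)
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, length(ds$y))
  ## degenerate inputs
  one_class <- hotspotr:::dataset_from_matrix(ds$X, rep(TRUE, 100))
  expect_error(train_svm(one_class, cfg), "single class")
  nf <- ds; nf$X[1, 1] <- NA
  expect_error(train_svm(nf, cfg), "non-finite")
})

test_that("prediction rejects mismatched feature schemas", {
  ds <- make_synthetic_dataset(n = 60, d = 4, seed = 3)
  m <- train_svm(ds, fast_cfg())
  shuffled <- ds$X[, rev(colnames(ds$X))]
  expect_error(predict_svm(m, shuffled), "schema")
  unnamed <- ds$X; colnames(unnamed) <- NULL
  expect_error(predict_svm(m, unnamed), "schema")
})

test_that("persisted models reproduce decision scores bit-identically", {
  ds <- make_synthetic_dataset(n = 80, d = 2, seed = 4)
  m <- train_svm(ds, fast_cfg())
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict_svm(m, ds$X)$score, predict_svm(m2, ds$X)$score)
})

test_that("metric formulas match their definitions and conventions", {
  m <- eval_metrics(2, 0, 0, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(m$f1, 0.8)
  m <- eval_metrics(5, 1, 0, 1)
  expect_equal(m$precision, 5 / 6)
  expect_equal(m$recall, 5 / 6)
  expect_equal(m$f1, 5 / 6)
  m <- eval_metrics(0, 0, 10, 5)
  expect_equal(c(m$precision, m$recall, m$f1), c(0, 0, 0))
  expect_true(m$degenerate)
  expect_error(eval_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("ROC handles perfect ranking, ties, and equals the rank statistic", {
  expect_equal(roc_auc(c(3, 2, 1, -1, -2), c(T, T, T, F, F))$auc, 1.0)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
  for (seed in 1:10) {
    set.seed(seed)
    sc <- sample(rnorm(30), 50, replace = TRUE)  # forces ties
    lb <- runif(50) < 0.4
    if (length(unique(lb)) < 2) next
    auc <- roc_auc(sc, lb)$auc
    u <- wilcox.test(sc[lb], sc[!lb], exact = FALSE)$statistic /
      (sum(lb) * sum(!lb))
    expect_equal(auc, unname(u), tolerance = 1e-9)
    ## invariance under strictly monotone transform
    expect_equal(roc_auc(exp(sc / 3), lb)$auc, auc, tolerance = 1e-12)
    ## independent implementation cross-check
    if (requireNamespace("pROC", quietly = TRUE)) {
      pr <- pROC::auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<"))
      expect_equal(auc, as.numeric(pr), tolerance = 1e-9)
    }
  }
})

test_that("cross-validation is seeded, pooled, and near-perfect when separable", {
  ds <- make_synthetic_dataset(n = 120, prevalence = 0.5, d = 6, seed = 5)
  r1 <- cross_validate(ds, fast_cfg(seed = 9))
  r2 <- cross_validate(ds, fast_cfg(seed = 9))
  expect_identical(r1$f1, r2$f1)
  expect_gte(r1$f1, 0.97)
  expect_equal(r1$tp + r1$fp + r1$tn + r1$fn, 120)
  expect_error(cross_validate(ds, fast_cfg(folds = 121)), "folds")
  ## different seed gives a different fold assignment
  expect_false(identical(hotspotr:::fold_assignment(ds$y, 10, 1),
                         hotspotr:::fold_assignment(ds$y, 10, 2)))
})

test_that("label-shuffled data cross-validate at chance level", {
  aucs <- vapply(1:8, function(seed) {
    ds <- make_synthetic_dataset(n = 200, prevalence = 0.5, d = 0,
                                 seed = seed)
    cross_validate(ds, fast_cfg(seed = seed))$auc
  }, 0)
  expect_true(mean(aucs >= 0.38 & aucs <= 0.62) >= 0.875)
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("self-consistency is at least as optimistic as cross-validation", {
  diffs <- vapply(1:10, function(seed) {
    ds <- make_synthetic_dataset(n = 120, d = 1, seed = seed)
    self_consistency(ds, fast_cfg(seed = seed))$f1 -
      cross_validate(ds, fast_cfg(seed = seed))$f1
  }, 0)
  expect_gte(mean(diffs), 0)
})

test_that("ablation attributes signal to the planted group only", {
  ds <- make_synthetic_dataset(n = 200, d = 2, groups = c(grpA = 4, grpB = 4),
                               informative = "grpA", seed = 11)
  tab <- ablate_features(ds, fast_cfg(seed = 11))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$group[which.min(tab$delta_f1)], "grpA")
  expect_lt(tab$delta_f1[tab$group == "grpA"], -0.1)
  ## ablating pure noise barely moves F1
  null_deltas <- vapply(1:6, function(seed) {
    d <- make_synthetic_dataset(n = 200, d = 2,
                                groups = c(grpA = 4, grpB = 4),
                                informative = "grpA", seed = seed)
    t <- ablate_features(d, fast_cfg(seed = seed), groups = "grpB")
    t$delta_f1
  }, 0)
  expect_lt(abs(mean(null_deltas)), 0.05)
  ## removing everything is an error
  sub <- ds; sub$X <- ds$X[, ds$feature_groups$grpA, drop = FALSE]
  sub$feature_groups <- ds$feature_groups["grpA"]
  expect_error(ablate_features(sub, fast_cfg(), groups = "grpA"), "empties")
})

test_that("random baseline matches closed forms", {
  ## predicting everything positive: F1 = 2p/(1+p) with prevalence p
  rb <- random_baseline(100, 40, replicates = 5, seed = 1, n_pred = 100)
  p <- 0.4
  expect_equal(rb$f1, 2 * p / (1 + p), tolerance = 1e-12)
  rb0 <- random_baseline(100, 40, replicates = 5, seed = 1, n_pred = 0)
  expect_equal(rb0$f1, 0)
  expect_error(random_baseline(10, 20), "more positives")
  ## equal predicted and true counts: P = R = F1 = E[TP]/n_pos
  rb <- random_baseline(377, 182, replicates = 400, seed = 3)
  expect_equal(rb$precision, rb$recall)
  expect_equal(rb$f1, 182 / 377, tolerance = 0.01)
})

test_that("group comparison reports means and two-sample p-values", {
  x <- rnorm(50, 0, 1)
  same <- compare_groups(x, x)
  expect_equal(same$diff, 0)
  expect_gt(same$p_value, 0.99)
  set.seed(2)
  res <- compare_groups(rnorm(50, 3, 1), rnorm(50, 0, 1))
  expect_lt(res$p_value, 1e-10)
  expect_gt(res$diff, 2)
  swapped <- compare_groups(rnorm(50, 0, 1), rnorm(50, 3, 1))
  expect_lt(swapped$diff, 0)
  ## rank-based alternative
  res_w <- compare_groups(rnorm(30, 2, 1), rnorm(30, 0, 1),
                          method = "wilcoxon")
  expect_lt(res_w$p_value, 1e-5)
  expect_error(compare_groups(1, 1:5), "at least 2")
})
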