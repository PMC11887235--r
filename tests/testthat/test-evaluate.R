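test_that("binary metric arithmetic and undefined-denominator policy", {
  bm <- binary_metrics(3, 5, 1, 1)
  expect_equal(bm[["accuracy"]], 0.8)
  expect_equal(bm[["sensitivity"]], 0.75)
  expect_equal(bm[["specificity"]], 5 / 6)
  # the never-positive classifier: sensitivity 0, specificity 1, balanced 0.5
  bm0 <- binary_metrics(0, 57, 0, 43)
  expect_equal(bm0[["sensitivity"]], 0)
  expect_equal(bm0[["specificity"]], 1)
  expect_equal(bm0[["balanced_accuracy"]], 0.5)
  # empty negative class: specificity undefined, balanced over defined parts
  bm1 <- binary_metrics(10, 0, 0, 0)
  expect_equal(bm1[["sensitivity"]], 1)
  expect_true(is.na(bm1[["specificity"]]))
  expect_equal(bm1[["balanced_accuracy"]], 1)
  expect_error(binary_metrics(0, 0, 0, 0), "zero")
})

test_that("ROC endpoints, monotonicity, symmetry and tie handling", {
  r <- roc_curve(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_equal(roc_curve(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  set.seed(3)
  truth <- runif(40) > 0.5
  truth[1:2] <- c(TRUE, FALSE)
  sc <- round(runif(40), 1)        # force ties
  r1 <- roc_curve(truth, sc)
  r2 <- roc_curve(truth, -sc)
  expect_equal(r2$auc, 1 - r1$auc, tolerance = 1e-12)
  expect_true(all(diff(r1$points$fpr) >= 0))
  expect_true(all(diff(r1$points$tpr) >= 0))
  expect_error(roc_curve(c(TRUE, TRUE), c(1, 2)), "both classes")
})

test_that("AUC equals the brute-force pairwise oracle (and pROC agrees)", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    truth <- runif(n) > 0.4
    if (length(unique(truth)) < 2) truth[1:2] <- c(TRUE, FALSE)
    sc <- sample(seq(0, 1, 0.05), n, TRUE)
    expect_equal(roc_curve(truth, sc)$auc, pairwise_auc(truth, sc),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(2)
  truth <- runif(60) > 0.5; sc <- rnorm(60)
  expect_equal(roc_curve(truth, sc)$auc,
               as.numeric(pROC::auc(pROC::roc(truth, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("stage metrics: perfect predictions, confusion trace, random AUC", {
  truth <- rep(1:4, times = c(10, 12, 8, 10))
  rep1 <- stage_metrics(truth, truth)
  expect_true(all(rep1$per_stage$accuracy == 1))
  expect_true(all(rep1$per_stage$balanced_accuracy == 1))
  expect_equal(sum(diag(rep1$confusion)), length(truth))
  expect_equal(rowSums(rep1$confusion), table(factor(truth, 1:4)),
               ignore_attr = TRUE)
  # probability input: perfect one-hot rows give AUC 1
  probs <- diag(4)[truth, ]
  expect_true(all(stage_metrics(truth, probs)$per_stage$auc == 1))
  # uniform random probabilities: AUC ~ 0.5 per stage
  set.seed(8)
  n <- 2000
  tr <- sample.int(4, n, TRUE)
  pr <- matrix(runif(4 * n), n, 4); pr <- pr / rowSums(pr)
  rep2 <- stage_metrics(tr, pr)
  expect_true(all(abs(rep2$per_stage$auc - 0.5) < 0.05))
  # confusion trace equals exact-match count
  pred <- sample.int(4, n, TRUE)
  expect_equal(sum(diag(stage_metrics(tr, pred)$confusion)),
               sum(tr == pred))
})

test_that("k-fold splits partition the data and respect patient groups", {
  m <- dataset_manifest(sprintf("img%03d.png", 1:100),
                        rep_len(1:4, 100),
                        sprintf("pat%02d", rep(1:25, each = 4)))
  folds <- kfold_split(m, k = 10, seed = 5)
  test_sets <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), 1:100)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(m$patient_id[f$train], m$patient_id[f$test]), 0)
  }
  expect_identical(kfold_split(m, k = 10, seed = 5), folds)
  expect_false(identical(kfold_split(m, k = 10, seed = 6), folds))
  expect_error(kfold_split(m, k = 30, seed = 1), "exceeds")
  # ungrouped: exact 10-by-10 partition
  ug <- kfold_split(m, k = 10, seed = 1, group_by_patient = FALSE)
  expect_true(all(vapply(ug, function(f) length(f$test), integer(1)) == 10L))
})
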