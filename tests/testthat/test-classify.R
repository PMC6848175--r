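test_that("classification metrics follow the recall conventions exactly", {
  # recalls 22/31 (MSA) and 56/65 (PD)
  true <- c(rep("MSA", 31), rep("PD", 65))
  pred <- c(rep("MSA", 22), rep("PD", 9), rep("PD", 56), rep("MSA", 9))
  m <- classification_metrics(true, pred, positive = "MSA")
  expect_equal(round(m$sensitivity, 2), 0.71)
  expect_equal(round(m$specificity, 2), 0.86)
  expect_equal(round(m$balanced_accuracy, 2), 0.79)
  expect_equal(m$balanced_accuracy, (22 / 31 + 56 / 65) / 2)  # exact identity
  expect_equal(m$accuracy, 78 / 96)
  all_right <- classification_metrics(true, true, positive = "MSA")
  expect_equal(all_right$balanced_accuracy, 1)
  flip <- classification_metrics(c("MSA", "MSA", "PD", "PD"),
                                 c("PD", "PD", "PD", "PD"), positive = "MSA")
  expect_equal(flip$sensitivity, 0)
  expect_equal(flip$specificity, 1)
  expect_equal(flip$balanced_accuracy, 0.5)
})

test_that("feature stability is a per-fold selection frequency", {
  lists <- list(c("a", "b"), c("a"), c("a", "c"), c("a", "b"))
  st <- feature_stability(lists)
  expect_equal(st[["a"]], 1)
  expect_equal(st[["b"]], 0.5)
  expect_equal(st[["c"]], 0.25)
  # oracle recount
  for (f in names(st)) {
    expect_equal(st[[f]], sum(vapply(lists, function(v) f %in% v, logical(1))) / 4)
  }
})

test_that("tune_svm separates separable data and is deterministic", {
  set.seed(450)
  x <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("a", "b"), each = 20))
  set.seed(1); t1 <- tune_svm(x, y)
  set.seed(1); t2 <- tune_svm(x, y)
  expect_identical(t1$cost, t2$cost)
  expect_equal(t1$cv_accuracy, 1)
  expect_true(all(predict(t1$model, x) == y))
  expect_error(tune_svm(x, factor(rep("a", 40))), "2 classes")
})

test_that("RFE keeps informative features and matches best-subset on a clear case", {
  set.seed(451)
  n <- 40
  informative <- c(rnorm(n / 2, -5), rnorm(n / 2, 5))  # unambiguous separation
  x <- cbind(informative, matrix(rnorm(n * 4), n, 4))
  colnames(x) <- c("signal", paste0("noise", 1:4))
  y <- factor(rep(c("a", "b"), each = n / 2))
  sel <- rfe_select(scale(x), y)
  expect_true("signal" %in% sel)
  # single feature in -> single feature out
  expect_identical(rfe_select(x[, 1, drop = FALSE], y), "signal")
  # 3 features, one perfectly separating: RFE's choice equals the exhaustive
  # best subset by inner-CV accuracy with ties toward fewer features
  x3 <- scale(x[, 1:3])
  set.seed(2)
  expect_identical(rfe_select(x3, y), "signal")
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(colnames(x3), k, simplify = FALSE)), recursive = FALSE)
  set.seed(3)
  fold <- subconn:::stratified_folds(y, 5)
  acc <- vapply(subsets, function(fs)
    subconn:::cv_accuracy(x3[, fs, drop = FALSE], y, 1, fold), numeric(1))
  best <- subsets[[which(acc == max(acc))[which.min(lengths(subsets)[acc == max(acc)])]]]
  expect_identical(best, "signal")
})

test_that("LOOCV separates a strongly separated cohort and stays at chance on null", {
  cfg <- classifier_config(tfnbs = tfnbs_config(n_perm = 99), seed = 11)
  sep <- two_group_cohort(n_per = 8, k_sep = 1, d = 10, seed = 452)
  rep_sep <- loocv_classify(sep, contrast = c("MSA", "PD"), config = cfg)
  expect_equal(rep_sep$metrics$sensitivity, 1)
  expect_equal(rep_sep$metrics$specificity, 1)
  # the separated edge is selected in every fold
  expect_equal(rep_sep$stability[[edge_index()$name[1]]], 1)
  # null cohort: balanced accuracy inside the binomial 95% chance band
  nul <- two_group_cohort(n_per = 12, d = 0, seed = 453)
  rep_nul <- loocv_classify(nul, contrast = c("MSA", "PD"), config = cfg)
  half_width <- 1.96 * sqrt(0.25 / 24)
  expect_gt(rep_nul$metrics$balanced_accuracy, 0.5 - half_width)
  expect_lt(rep_nul$metrics$balanced_accuracy, 0.5 + half_width)
  # fallback path: with nothing significant, k_fallback features enter RFE
  expect_true(all(rep_nul$folds$n_features >= 1))
  # reproducibility
  rep_nul2 <- loocv_classify(nul, contrast = c("MSA", "PD"), config = cfg)
  expect_identical(rep_nul$folds, rep_nul2$folds)
})

test_that("the held-out subject cannot influence its fold's selection or tuning", {
  cfg <- classifier_config(tfnbs = tfnbs_config(n_perm = 99), seed = 21)
  coh <- two_group_cohort(n_per = 6, k_sep = 2, d = 3, seed = 454)
  r1 <- loocv_classify(coh, contrast = c("MSA", "PD"), config = cfg)
  # replace subject 3's matrix with arbitrary values
  coh2 <- coh
  coh2$matrices[, , 3] <- edge_unflatten(runif(153, 50, 60))
  r2 <- loocv_classify(coh2, contrast = c("MSA", "PD"), config = cfg)
  expect_identical(r1$fold_features[[3]], r2$fold_features[[3]])
  expect_identical(r1$folds$cost[3], r2$folds$cost[3])
  expect_identical(r1$folds$n_features[3], r2$folds$n_features[3])
})

test_that("scalar ROI features flow through the same nested pipeline", {
  set.seed(455)
  subj <- data.frame(id = sprintf("S%02d", 1:24),
                     group = rep(c("MSA", "PD"), each = 12),
                     gender = rep_len(c(0L, 1L), 24))
  arr <- array(0, c(18, 18, 24))
  for (k in 1:24) arr[, , k] <- edge_unflatten(runif(153, 1, 2))
  fa <- matrix(rnorm(24 * 18, 0.4, 0.03), 24, 18)
  fa[1:12, 1] <- fa[1:12, 1] - 0.15   # MSA effect on one ROI
  coh <- nos_cohort(arr, subj, features = list(FA = fa))
  cfg <- classifier_config(tfnbs = tfnbs_config(n_perm = 99), seed = 31)
  rep_fa <- loocv_classify(coh, contrast = c("MSA", "PD"), features = "FA",
                           config = cfg)
  expect_gt(rep_fa$metrics$balanced_accuracy, 0.8)
  expect_gt(rep_fa$stability[[paste0("FA:", subcortical_atlas()[1])]], 0.8)
  expect_error(loocv_classify(coh, features = "MD", config = cfg),
               "no feature table")
})
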