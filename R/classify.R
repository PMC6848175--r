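#' Configuration for the nested LOOCV classifier
#'
#' @param c_grid SVM cost values searched by the inner grid search
#'   (default `10^(-3:3)`).
#' @param inner_folds stratified inner cross-validation folds (default 5).
#' @param rfe_step features removed per elimination round (default 1).
#' @param k_fallback when a training fold yields no significant edges, the
#'   `k_fallback` edges with the highest enhanced scores are used instead
#'   (default 10).
#' @param tfnbs a [tfnbs_config()] for the per-fold feature-selection stage;
#'   defaults to 1000 permutations for tractability inside the outer loop.
#' @param seed optional integer seed; each outer fold derives its own
#'   sub-seed so results are reproducible and folds are independent.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(c_grid = 10^(-3:3), inner_folds = 5,
                              rfe_step = 1, k_fallback = 10,
                              tfnbs = tfnbs_config(n_perm = 1000),
                              seed = NULL) {
  stopifnot(length(c_grid) >= 1, inner_folds >= 2, rfe_step >= 1,
            k_fallback >= 1)
  structure(list(c_grid = sort(c_grid), inner_folds = inner_folds,
                 rfe_step = rfe_step, k_fallback = k_fallback,
                 tfnbs = tfnbs, seed = seed),
            class = "classifier_config")
}

# Stratified k-fold assignment: within each class, subjects are shuffled and
# dealt round-robin. Uses the current RNG stream.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Per-feature weights of a fitted linear SVM: w = t(coefs) %*% SV.
svm_weights <- function(model) {
  drop(crossprod(model$coefs, model$SV))
}

# Inner-CV accuracy of a linear SVM at cost `cost` on (x, y) given a fold
# assignment. Standardization is the caller's responsibility.
cv_accuracy <- function(x, y, cost, fold) {
  correct <- 0L
  for (f in unique(fold)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                    cost = cost, scale = FALSE)
    pred <- stats::predict(m, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Grid-search tuning of a linear SVM
#'
#' Chooses the cost `C` maximizing stratified inner cross-validated accuracy
#' (ties broken toward the smallest `C`, i.e. the widest margin), then refits
#' on the full training data. Features are expected to be standardized by
#' the caller with training-fold statistics.
#'
#' @param x numeric feature matrix (training fold).
#' @param y factor of two class labels.
#' @param config a [classifier_config()].
#' @return List with `model` (fitted [e1071::svm()]), `cost`, and
#'   `cv_accuracy` at the chosen cost.
#' @export
tune_svm <- function(x, y, config = classifier_config()) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("need exactly 2 classes")
  if (length(config$c_grid) == 0) stop("empty C grid")
  k <- min(config$inner_folds, min(table(y)))
  fold <- stratified_folds(y, k)
  acc <- vapply(config$c_grid, function(C) cv_accuracy(x, y, C, fold),
                numeric(1))
  best <- which.max(acc)  # ties -> first, i.e. smallest C (grid is sorted)
  model <- e1071::svm(x, y, kernel = "linear", cost = config$c_grid[best],
                      scale = FALSE)
  list(model = model, cost = config$c_grid[best], cv_accuracy = acc[best])
}

#' Recursive feature elimination for a linear SVM
#'
#' Ranks features by iteratively refitting a linear SVM (at `C = 1`) and
#' dropping the `rfe_step` features with the smallest squared weights; the
#' retained subset size is the one maximizing stratified inner
#' cross-validated accuracy along the elimination path, ties broken toward
#' fewer features.
#'
#' @param x standardized feature matrix with column names.
#' @param y factor of two class labels.
#' @param config a [classifier_config()].
#' @return Character vector of selected feature names.
#' @export
rfe_select <- function(x, y, config = classifier_config()) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("need exactly 2 classes")
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  if (ncol(x) == 1L) return(colnames(x))
  k <- min(config$inner_folds, min(table(y)))
  fold <- stratified_folds(y, k)
  active <- colnames(x)
  path <- list(active)
  while (length(active) > 1L) {
    m <- e1071::svm(x[, active, drop = FALSE], y, kernel = "linear",
                    cost = 1, scale = FALSE)
    w2 <- svm_weights(m)^2
    drop_n <- min(config$rfe_step, length(active) - 1L)
    active <- active[order(w2, decreasing = TRUE)][seq_len(length(active) - drop_n)]
    path[[length(path) + 1L]] <- active
  }
  acc <- vapply(path, function(feats)
    cv_accuracy(x[, feats, drop = FALSE], y, 1, fold), numeric(1))
  sizes <- lengths(path)
  best <- which(acc == max(acc, na.rm = TRUE))
  best <- best[which.min(sizes[best])]  # ties -> fewer features
  path[[best]]
}

#' Per-fold feature selection: omnibus network test then RFE
#'
#' Stage 1 runs the TFNBS group comparison on the training subjects only and
#' keeps the FDR-significant edges; if none are significant, the
#' `k_fallback` edges with the highest enhanced scores are used. Stage 2
#' runs [rfe_select()] on the surviving features (standardized with
#' training statistics).
#'
#' @param train_cohort training-fold [nos_cohort()] (test subject excluded).
#' @param config a [classifier_config()].
#' @param covariates covariate columns for the TFNBS stage.
#' @return Character vector of selected edge names, with the stage-1
#'   (pre-RFE) edge set in attribute `"stage1"`.
#' @export
select_features_fold <- function(train_cohort, config = classifier_config(),
                                 covariates = "gender") {
  res <- tfnbs_inference(train_cohort, config$tfnbs, covariates = covariates)
  feats <- res$significant
  if (length(feats) == 0L) {
    ord <- order(res$stats$score, decreasing = TRUE)
    feats <- res$stats$name[ord][seq_len(min(config$k_fallback, nrow(res$stats)))]
  }
  stage1 <- feats
  E <- cohort_edges(train_cohort)
  x <- scale(E[, feats, drop = FALSE])
  keep <- attr(x, "scaled:scale") > 0
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0L) stop("all selected features are constant in the training fold")
  y <- factor(train_cohort$subjects$group)
  structure(rfe_select(x, y, config), stage1 = stage1)
}

# Build the subjects-by-features matrix for a feature-set request.
feature_matrix <- function(cohort, features) {
  blocks <- list()
  for (f in features) {
    if (f == "nos") {
      blocks[[f]] <- cohort_edges(cohort)
    } else {
      if (is.null(cohort$features[[f]]))
        stop("cohort has no feature table '", f, "'")
      ft <- cohort$features[[f]]
      colnames(ft) <- paste(f, colnames(ft), sep = ":")
      blocks[[f]] <- ft
    }
  }
  do.call(cbind, blocks)
}

# Stage-1 selection for scalar ROI features: per-feature permutation GLM F
# with FDR, falling back to the k highest F when nothing is significant.
select_scalar_features <- function(X, group, covariates, config) {
  d <- group_designs(group, covariates)
  f_obs <- glm_f_matrix(X, designs = d)
  b <- rep(0L, ncol(X))
  for (r in seq_len(config$tfnbs$n_perm)) {
    dp <- group_designs(sample(group), covariates, check_rank = FALSE)
    b <- b + (glm_f_matrix(X, designs = dp) >= f_obs - 1e-12)
  }
  p <- (b + 1) / (config$tfnbs$n_perm + 1)
  fdr <- bh_fdr(p, config$tfnbs$fdr_q)
  feats <- colnames(X)[fdr$rejected]
  if (length(feats) == 0L) {
    feats <- colnames(X)[order(f_obs, decreasing = TRUE)][
      seq_len(min(config$k_fallback, ncol(X)))]
  }
  feats
}

#' Nested leave-one-out classification of a two-group cohort
#'
#' One subject at a time is held out; on the remaining N-1 subjects the full
#' selection pipeline runs from scratch — omnibus network (or per-feature)
#' permutation test, recursive feature elimination, and cross-validated grid
#' search for the SVM cost — and the tuned linear SVM predicts the held-out
#' subject. The held-out subject never influences filtering, selection,
#' standardization, or tuning.
#'
#' @param cohort a [nos_cohort()] (subset to the contrast's two groups, or
#'   pass `contrast`).
#' @param contrast length-2 character vector of group labels, e.g.
#'   `c("MSA", "PD")`; the first is the positive class whose recall is
#'   reported as sensitivity.
#' @param features feature sets to concatenate: `"nos"` (edges) and/or names
#'   of cohort feature tables such as `"FA"`, `"MD"`, `"volume"`
#'   (default `"nos"`).
#' @param config a [classifier_config()].
#' @param covariates covariate columns for the selection stage.
#' @return Object of class `classification_report`: list with `folds`
#'   (data.frame: `id`, `true`, `predicted`, `cost`, `n_features`),
#'   `fold_features` (list of selected-feature vectors), `metrics` (from
#'   [classification_metrics()]), `stability` (from [feature_stability()]),
#'   `positive` class.
#' @export
loocv_classify <- function(cohort, contrast = c("MSA", "PD"),
                           features = "nos", config = classifier_config(),
                           covariates = "gender") {
  stopifnot(inherits(cohort, "nos_cohort"))
  cohort <- subset_cohort(cohort, cohort$subjects$group %in% contrast)
  y_all <- factor(cohort$subjects$group, levels = contrast)
  if (any(table(y_all) < 3)) stop("need at least 3 subjects per class for LOOCV")
  n <- nrow(cohort$subjects)
  X_all <- feature_matrix(cohort, features)
  use_edges <- identical(features, "nos")
  base_seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)

  fold_rows <- vector("list", n)
  fold_feats <- vector("list", n)
  fold_stage1 <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((base_seed + i) %% .Machine$integer.max)
    train <- setdiff(seq_len(n), i)
    tr_cohort <- subset_cohort(cohort, train)
    if (use_edges) {
      feats <- select_features_fold(tr_cohort, config, covariates)
      fold_stage1[[i]] <- attr(feats, "stage1")
      feats <- as.character(feats)
    } else {
      Xtr0 <- X_all[train, , drop = FALSE]
      keep0 <- apply(Xtr0, 2, stats::sd) > 0
      covs <- if (is.null(covariates)) NULL else
        tr_cohort$subjects[, covariates, drop = FALSE]
      stage1 <- select_scalar_features(Xtr0[, keep0, drop = FALSE],
                                       y_all[train], covs, config)
      fold_stage1[[i]] <- stage1
      xs <- scale(Xtr0[, stage1, drop = FALSE])
      feats <- rfe_select(xs, y_all[train], config)
    }
    ctr <- colMeans(X_all[train, feats, drop = FALSE])
    scl <- apply(X_all[train, feats, drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    x_tr <- scale(X_all[train, feats, drop = FALSE], center = ctr, scale = scl)
    tuned <- tune_svm(x_tr, y_all[train], config)
    x_te <- scale(X_all[i, feats, drop = FALSE], center = ctr, scale = scl)
    pred <- as.character(stats::predict(tuned$model, x_te))
    fold_rows[[i]] <- data.frame(
      id = cohort$subjects$id[i],
      true = as.character(y_all[i]), predicted = pred,
      cost = tuned$cost, n_features = length(feats),
      stringsAsFactors = FALSE
    )
    fold_feats[[i]] <- feats
  }
  folds <- do.call(rbind, fold_rows)
  names(fold_feats) <- folds$id
  names(fold_stage1) <- folds$id
  structure(
    list(folds = folds, fold_features = fold_feats,
         fold_stage1 = fold_stage1,
         metrics = classification_metrics(folds$true, folds$predicted,
                                          positive = contrast[1]),
         stability = feature_stability(fold_feats),
         stage1_stability = feature_stability(fold_stage1),
         positive = contrast[1]),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "LOOCV report (%d folds, positive class %s)\n  accuracy %.2f | balanced accuracy %.2f | sensitivity %.2f | specificity %.2f\n",
    nrow(x$folds), x$positive, m$accuracy, m$balanced_accuracy,
    m$sensitivity, m$specificity))
  stable <- x$stability[x$stability > 0.8]
  if (length(stable))
    cat("  features selected in >80% of folds:",
        paste(names(stable), collapse = ", "), "\n")
  invisible(x)
}

#' Classification performance metrics
#'
#' Sensitivity is the recall of the positive class (here, MSA); specificity
#' the recall of the other class; raw accuracy is correct/total; balanced
#' accuracy the mean of the two recalls. Both accuracies are reported —
#' balanced accuracy is the reference summary, since it is the convention
#' consistent with the published per-contrast tables.
#'
#' @param true,predicted aligned label vectors.
#' @param positive label of the positive class.
#' @return List with `accuracy`, `balanced_accuracy`, `sensitivity`,
#'   `specificity`, `n`.
#' @export
classification_metrics <- function(true, predicted, positive) {
  stopifnot(length(true) == length(predicted), length(true) > 0)
  pos <- true == positive
  if (!any(pos) || all(pos)) stop("both classes must appear among true labels")
  sens <- mean(predicted[pos] == true[pos])
  spec <- mean(predicted[!pos] == true[!pos])
  list(accuracy = mean(predicted == true),
       balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens, specificity = spec,
       n = length(true))
}

#' Feature selection frequency across folds
#'
#' @param fold_features list of per-fold selected-feature character vectors.
#' @return Named numeric vector: fraction of folds selecting each feature,
#'   sorted decreasing.
#' @export
feature_stability <- function(fold_features) {
  stopifnot(length(fold_features) >= 1)
  all_feats <- unique(unlist(fold_features))
  freq <- vapply(all_feats, function(f)
    mean(vapply(fold_features, function(v) f %in% v, logical(1))),
    numeric(1))
  sort(freq, decreasing = TRUE)
}
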