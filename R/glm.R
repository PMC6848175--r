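# Design matrices for the group GLM: full model (intercept + group dummies +
# covariates) and reduced model (intercept + covariates). Covariates may be a
# vector, matrix or data.frame.
# `check_rank = FALSE` is used inside permutation loops: a permuted label
# vector can by chance be collinear with a covariate, which the pivoted QR
# handles (the group effect is then absorbed, F = 0 for that draw).
group_designs <- function(group, covariates = NULL, check_rank = TRUE) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("each group needs at least 2 subjects")
  n <- length(group)
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    if (nrow(C) != n) stop("covariates not aligned with subjects")
    storage.mode(C) <- "double"
  }
  X1 <- stats::model.matrix(~group)
  if (!is.null(C)) X1 <- cbind(X1, C)
  X0 <- cbind(`(Intercept)` = rep(1, n), C)
  if (check_rank && qr(X1)$rank < ncol(X1)) stop("rank-deficient design")
  list(X1 = X1, X0 = X0, df1 = nlevels(group) - 1L,
       df2 = n - ncol(X1), group = group)
}

# Partial F for the group factor, vectorized over the columns of Y.
glm_f_matrix <- function(Y, group, covariates = NULL, designs = NULL) {
  if (is.null(designs)) designs <- group_designs(group, covariates)
  Y <- as.matrix(Y)
  q1 <- qr(designs$X1); q0 <- qr(designs$X0)
  rss1 <- colSums(qr.resid(q1, Y)^2)
  rss0 <- colSums(qr.resid(q0, Y)^2)
  f <- ((rss0 - rss1) / designs$df1) / (rss1 / designs$df2)
  # zero residual variance with zero effect (constant y) is a 0/0: report 0
  f[rss0 < .Machine$double.eps * nrow(Y)] <- 0
  pmax(f, 0)
}

#' GLM F statistic for a group effect
#'
#' Partial F for the group factor in a general linear model, adjusting for
#' optional covariates: the reduction in residual sum of squares from adding
#' group indicators to an intercept + covariate model. With no covariates
#' this is the one-way ANOVA F. Invariant under affine rescaling of `y`.
#'
#' @param y numeric response vector (one value per subject).
#' @param group group labels (2+ levels, each with 2+ subjects).
#' @param covariates optional vector/matrix/data.frame of nuisance
#'   covariates (e.g. gender).
#' @return List with `statistic` (F), `df1`, `df2`.
#' @export
glm_f <- function(y, group, covariates = NULL) {
  d <- group_designs(group, covariates)
  if (length(y) != length(d$group)) stop("y not aligned with group labels")
  list(statistic = unname(glm_f_matrix(cbind(y), designs = d)),
       df1 = d$df1, df2 = d$df2)
}

# t statistics for the second-group indicator in a two-group GLM with
# covariates, vectorized over columns of Y. Sign convention: positive t means
# the second level of factor(group) has the larger adjusted mean.
glm_t_matrix <- function(Y, group, covariates = NULL, designs = NULL) {
  if (is.null(designs)) designs <- group_designs(group, covariates)
  if (designs$df1 != 1L) stop("t contrast requires exactly 2 groups")
  Y <- as.matrix(Y)
  X1 <- designs$X1
  q1 <- qr(X1)
  coefs <- qr.coef(q1, Y)
  rss1 <- colSums(qr.resid(q1, Y)^2)
  sigma2 <- rss1 / designs$df2
  xtxinv <- chol2inv(qr.R(q1))
  j <- 2L  # the group indicator column in ~group
  se <- sqrt(sigma2 * xtxinv[j, j])
  t <- coefs[j, ] / se
  t[!is.finite(t)] <- 0  # aliased or zero-variance fits carry no group signal
  t
}

#' One-way ANOVA F from group summary statistics
#'
#' Closed-form F from per-group means, SDs and sizes:
#' \deqn{F = \frac{\sum_i n_i (m_i - \bar m)^2 / (k-1)}
#'            {\sum_i (n_i - 1) s_i^2 / (N-k)}}
#' Useful as an oracle to check published table statistics computable from
#' printed summaries.
#'
#' @param means,sds,ns per-group means, sample SDs, sizes (equal lengths,
#'   k >= 2, all `ns >= 2`).
#' @return List with `statistic`, `df1`, `df2`.
#' @export
anova_f_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k) stop("need k >= 2 aligned groups")
  if (any(ns < 2)) stop("each group needs n >= 2")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  msb <- sum(ns * (means - gm)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (N - k)
  if (msw == 0) stop("zero pooled within-group variance")
  list(statistic = msb / msw, df1 = k - 1L, df2 = as.integer(N - k))
}

#' Pooled-variance two-sample t statistic
#'
#' Either from raw samples (`y1`, `y2`) or from summary statistics
#' (`means`, `sds`, `ns`). The pooled-variance (not Welch) convention is the
#' one that reproduces published two-group table statistics here.
#'
#' @param y1,y2 numeric samples, or `NULL` when using summaries.
#' @param means,sds,ns length-2 summaries (used when `y1` is `NULL`).
#' @return List with `statistic` (t, sign of `mean1 - mean2`) and `df`.
#' @export
two_sample_t <- function(y1 = NULL, y2 = NULL, means = NULL, sds = NULL, ns = NULL) {
  if (!is.null(y1)) {
    means <- c(mean(y1), mean(y2))
    sds <- c(stats::sd(y1), stats::sd(y2))
    ns <- c(length(y1), length(y2))
  }
  if (any(ns < 2)) stop("each group needs n >= 2")
  sp2 <- ((ns[1] - 1) * sds[1]^2 + (ns[2] - 1) * sds[2]^2) / (sum(ns) - 2)
  if (sp2 == 0) stop("zero pooled variance")
  list(statistic = (means[1] - means[2]) / sqrt(sp2 * (1 / ns[1] + 1 / ns[2])),
       df = as.integer(sum(ns) - 2))
}

# All permutations of 1..n as an n! x n matrix (n <= 8).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L), drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Permutation p-value for a group-effect statistic
#'
#' Shuffles group labels while holding covariate values attached to their
#' subjects, recomputes the statistic, and reports
#' \eqn{p = (b + 1) / (m + 1)} where `b` counts permuted statistics at least
#' as extreme as the observed one (upper tail for F; absolute value for
#' two-tailed t). The +1 convention never returns an exactly zero p.
#'
#' @param y response vector.
#' @param group group labels.
#' @param covariates optional nuisance covariates (held fixed).
#' @param stat `"F"` (upper tail), `"t"` (two-tailed, two groups), or a
#'   function `(y, group, covariates) -> scalar`.
#' @param n_perm number of Monte-Carlo permutations (default 10000).
#' @param exact if `TRUE`, enumerate all `n!` label permutations instead of
#'   sampling (feasible for n <= 8); p is then the exact proportion of
#'   permutations (identity included) at least as extreme as observed.
#' @param tail `"upper"` or `"two-sided"`; defaults to the convention of
#'   `stat`.
#' @param seed optional integer seed (local to this call).
#' @return List with `statistic`, `p`, `n_perm`.
#' @export
permutation_p <- function(y, group, covariates = NULL, stat = "F",
                          n_perm = 10000, exact = FALSE, tail = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.function(stat)) {
    stat_fn <- function(g) stat(y, g, covariates)
    if (is.null(tail)) tail <- "upper"
  } else if (stat == "F") {
    group_designs(group, covariates)  # validate the observed design
    stat_fn <- function(g) glm_f_matrix(
      cbind(y), designs = group_designs(g, covariates, check_rank = FALSE))
    if (is.null(tail)) tail <- "upper"
  } else if (stat == "t") {
    group_designs(group, covariates)
    stat_fn <- function(g) glm_t_matrix(
      cbind(y), designs = group_designs(g, covariates, check_rank = FALSE))
    if (is.null(tail)) tail <- "two-sided"
  } else stop("unknown stat")
  obs <- stat_fn(group)
  extreme <- function(s) {
    if (tail == "two-sided") abs(s) >= abs(obs) - 1e-12 else s >= obs - 1e-12
  }
  n <- length(group)
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    P <- all_permutations(n)
    vals <- apply(P, 1, function(ix) stat_fn(group[ix]))
    p <- mean(extreme(vals))
    return(list(statistic = unname(obs), p = p, n_perm = nrow(P)))
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  b <- 0L
  for (r in seq_len(n_perm)) {
    if (extreme(stat_fn(sample(group)))) b <- b + 1L
  }
  list(statistic = unname(obs), p = (b + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR on a vector of p-values. Adjusted p-values come from
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p p-values in (0, 1].
#' @param q target FDR level (default 0.05).
#' @return List with `adjusted` (BH-adjusted p) and `rejected` (logical).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Spearman rank correlation
#'
#' Tie-corrected Spearman rho with its p-value, via [stats::cor.test()].
#'
#' @param x,y numeric vectors (n >= 3).
#' @return List with `estimate` (rho) and `p`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) stop("need aligned n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(estimate = unname(ct$estimate), p = ct$p.value)
}

#' Pairwise post-hoc contrasts on selected edges
#'
#' For each requested group pair and each edge (typically the subnetwork
#' already declared significant by the omnibus TFNBS test), computes the
#' covariate-adjusted two-group GLM t statistic, a two-tailed permutation
#' p-value, and BH-FDR adjustment across the whole pair-by-edge family.
#'
#' @param cohort a [nos_cohort()].
#' @param edges edge positions, names or logical mask over the 153 edges.
#' @param pairs list of length-2 character vectors of group labels; default:
#'   all unordered pairs present in the cohort.
#' @param covariates character vector of subject-table columns to adjust for
#'   (default `"gender"`).
#' @param n_perm permutations per contrast (default 10000).
#' @param q FDR level (default 0.05).
#' @param seed optional integer seed (local to this call).
#' @return data.frame, one row per pair x edge: `group_a`, `group_b`,
#'   `edge`, `roi_a`, `roi_b`, `t` (sign of adjusted `group_b - group_a`
#'   mean difference), `df`, `p_perm`, `p_fdr`, `significant`.
#' @export
pairwise_posthoc <- function(cohort, edges, pairs = NULL,
                             covariates = "gender", n_perm = 10000,
                             q = 0.05, seed = NULL) {
  stopifnot(inherits(cohort, "nos_cohort"))
  if (!is.null(seed)) set.seed(seed)
  E <- cohort_edges(cohort)
  if (is.logical(edges)) edges <- which(edges)
  if (is.character(edges)) edges <- match(edges, colnames(E))
  if (length(edges) == 0L || anyNA(edges)) stop("empty or unknown edge set")
  groups <- sort(unique(cohort$subjects$group))
  if (is.null(pairs)) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  }
  ei <- edge_index(cohort$labels)
  rows <- list()
  for (pr in pairs) {
    if (!all(pr %in% groups)) stop("pair refers to a group absent from the cohort: ",
                                   paste(pr, collapse = "-"))
    sel <- cohort$subjects$group %in% pr
    g <- factor(cohort$subjects$group[sel], levels = pr)
    covs <- if (is.null(covariates)) NULL else
      cohort$subjects[sel, covariates, drop = FALSE]
    Y <- E[sel, edges, drop = FALSE]
    d <- group_designs(g, covs)
    t_obs <- glm_t_matrix(Y, designs = d)
    b <- rep(0L, length(edges))
    for (r in seq_len(n_perm)) {
      gp <- sample(g)
      dp <- group_designs(gp, covs, check_rank = FALSE)
      t_perm <- glm_t_matrix(Y, designs = dp)
      b <- b + (abs(t_perm) >= abs(t_obs) - 1e-12)
    }
    rows[[paste(pr, collapse = "-")]] <- data.frame(
      group_a = pr[1], group_b = pr[2],
      edge = edges, roi_a = ei$roi_a[edges], roi_b = ei$roi_b[edges],
      t = unname(t_obs), df = d$df2,
      p_perm = (b + 1) / (n_perm + 1),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fdr <- bh_fdr(out$p_perm, q)
  out$p_fdr <- fdr$adjusted
  out$significant <- fdr$rejected
  out
}
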