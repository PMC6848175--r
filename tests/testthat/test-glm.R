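test_that("glm_f matches the lm residual-sum-of-squares oracle", {
  set.seed(420)
  for (r in 1:5) {
    n <- 40
    g <- sample(c("A", "B", "C"), n, replace = TRUE)
    covs <- data.frame(gender = rbinom(n, 1, 0.5), icv = rnorm(n))
    y <- rnorm(n) + (g == "C") * 0.5
    f1 <- glm_f(y, g)$statistic
    expect_equal(f1, oracle_glm_f(y, g), tolerance = 1e-10)
    f2 <- glm_f(y, g, covs)$statistic
    expect_equal(f2, oracle_glm_f(y, g, covs), tolerance = 1e-10)
    # affine invariance
    expect_equal(glm_f(3.7 * y - 11, g, covs)$statistic, f2, tolerance = 1e-8)
  }
  # grand-mean pattern by groups -> zero between-group signal
  g <- rep(c("A", "B"), each = 10)
  y <- rep(c(1, 2), 10)
  expect_equal(glm_f(y, g)$statistic, 0, tolerance = 1e-12)
  expect_error(glm_f(rnorm(4), c("A", "A", "A", "B")), "at least 2")
  expect_error(glm_f(rnorm(4), c("A", "A", "B", "B"),
                     covariates = c(0, 0, 1, 1)), "rank-deficient")
})

test_that("summary-statistic F and t agree with exact-summary reconstructions", {
  expect_error(anova_f_from_summary(c(1, 1), c(0, 0), c(5, 5)), "zero pooled")
  expect_equal(anova_f_from_summary(c(2, 2, 2), c(1, 2, 1), c(5, 6, 7))$statistic, 0)
  # reconstruct samples with exactly the requested mean/SD per group
  set.seed(421)
  means <- c(10, 12, 9); sds <- c(2, 3, 1.5); ns <- c(8, 10, 6)
  y <- c(); g <- c()
  for (k in 1:3) {
    x <- rnorm(ns[k])
    y <- c(y, means[k] + sds[k] * (x - mean(x)) / sd(x))
    g <- c(g, rep(LETTERS[k], ns[k]))
  }
  expect_equal(anova_f_from_summary(means, sds, ns)$statistic,
               glm_f(y, g)$statistic, tolerance = 1e-8)
  # two-group: t^2 = F, and raw/summary paths agree
  t_sum <- two_sample_t(means = means[1:2], sds = sds[1:2], ns = ns[1:2])
  expect_equal(t_sum$statistic^2,
               anova_f_from_summary(means[1:2], sds[1:2], ns[1:2])$statistic,
               tolerance = 1e-10)
  y1 <- y[g == "A"]; y2 <- y[g == "B"]
  expect_equal(two_sample_t(y1, y2)$statistic, t_sum$statistic, tolerance = 1e-8)
  expect_equal(two_sample_t(y1, y1)$statistic, 0)
})

test_that("permutation p matches exhaustive enumeration and its bounds", {
  set.seed(422)
  y <- c(0.1, 1.4, 2.2, 3.1, 4.9, 6.0)
  g <- c("A", "A", "A", "B", "B", "B")
  ex <- permutation_p(y, g, stat = "F", exact = TRUE)
  # independent oracle: enumerate all 720 index permutations directly
  perms <- subconn:::all_permutations(6)
  vals <- apply(perms, 1, function(ix) oracle_glm_f(y, g[ix]))
  expect_equal(ex$p, mean(vals >= ex$statistic - 1e-12))
  # Monte-Carlo estimate converges to the exact value
  mc <- permutation_p(y, g, stat = "F", n_perm = 4000, seed = 1)
  expect_lt(abs(mc$p - ex$p), 0.03)
  expect_gte(mc$p, 1 / 4001)
  expect_lte(mc$p, 1)
  # constant response: no signal, p = 1
  expect_equal(permutation_p(rep(2, 6), g, stat = "F", n_perm = 50, seed = 1)$p, 1)
  # overwhelming separation: observed beats every permutation
  y2 <- c(rnorm(20), rnorm(20, 5))
  g2 <- rep(c("A", "B"), each = 20)
  strong <- permutation_p(y2, g2, stat = "t", n_perm = 999, seed = 2)
  expect_equal(strong$p, 1 / 1000)
})

test_that("BH-FDR matches direct step-up evaluation and is calibrated", {
  expect_equal(sum(bh_fdr(rep(1, 20))$rejected), 0)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696,
         0.762, 0.94, 0.942, 0.975, 0.986)
  for (q in c(0.05, 0.1, 0.25)) {
    expect_equal(bh_fdr(p, q)$rejected, oracle_bh_reject(p, q))
  }
  expect_equal(sum(bh_fdr(p, 0.05)$rejected), 1)
  expect_equal(sum(bh_fdr(p, 0.25)$rejected), 6)  # p_(6) = 0.06 = 6q/m exactly
  # adjusted p nondecreasing in p-value rank
  adj <- bh_fdr(p)$adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "in \\(0, 1\\]")
  # independent nulls: mean false discovery proportion <= q
  set.seed(423)
  fdp <- replicate(1000, {
    r <- bh_fdr(runif(153), 0.05)$rejected
    if (any(r)) 1 else 0  # all nulls: any rejection is a false discovery
  })
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000) + 1e-9)
})

test_that("uncorrected permutation test holds its level under the null", {
  # 1000 null responses tested at once against a shared permutation stream
  set.seed(424)
  n <- 30
  g <- factor(rep(c("A", "B", "C"), each = 10))
  gender <- rbinom(n, 1, 0.5)
  Y <- matrix(rnorm(n * 1000), n, 1000)
  f_obs <- subconn:::glm_f_matrix(Y, g, gender)
  m <- 199
  b <- rep(0, 1000)
  for (r in seq_len(m)) {
    fp <- subconn:::glm_f_matrix(Y, sample(g), gender)
    b <- b + (fp >= f_obs - 1e-12)
  }
  p <- (b + 1) / (m + 1)
  rate <- mean(p <= 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("spearman_assoc matches the rank-then-Pearson oracle", {
  expect_equal(spearman_assoc(1:10, exp(1:10))$estimate, 1)
  expect_equal(spearman_assoc(1:10, -(1:10)^3)$estimate, -1)
  set.seed(425)
  x <- rnorm(40); y <- x + rnorm(40)
  expect_equal(spearman_assoc(x, y)$estimate,
               cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearman_assoc(rep(1, 10), rnorm(10)), "constant")
})

test_that("post-hoc contrasts reduce to the pooled t and control the family FDR", {
  set.seed(426)
  # two groups, no covariates: GLM contrast t equals the pooled two-sample t
  E <- matrix(runif(20 * 153, 1, 5), 20, 153)
  coh <- cohort_from_edges(E, groups = rep(c("A", "B"), each = 10))
  ph <- pairwise_posthoc(coh, edges = 1:4, covariates = NULL,
                         n_perm = 99, seed = 1)
  for (k in 1:4) {
    tt <- two_sample_t(E[1:10, k], E[11:20, k])$statistic
    expect_equal(ph$t[ph$edge == k], -tt, tolerance = 1e-10)  # sign: B - A
  }
  # identical groups: nothing significant at this seed
  expect_false(any(ph$significant))
  expect_error(pairwise_posthoc(coh, 1:2, pairs = list(c("A", "Z"))), "absent")
})
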