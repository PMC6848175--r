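test_that("parameter fixtures encode the published tables", {
  p <- nos_group_params()
  expect_identical(nrow(p), 10L)
  cereb <- p[p$roi_a == "Left-Cerebellum-White-Matter" &
               p$roi_b == "Right-Cerebellum-White-Matter", ]
  expect_equal(cereb$mean_MSA, 2.3522e6)
  expect_equal(cereb$sd_MSA, 1.032e6)
  fp <- feature_group_params()
  expect_equal(fp[fp$measure == "FA" & fp$roi == "Right-Cerebellum-White-Matter",
                  "mean_HC"], 0.3351)
  expect_equal(fp[fp$measure == "FA" & fp$roi == "Right-Cerebellum-White-Matter",
                  "sd_HC"], 0.026)
  expect_equal(fp[fp$measure == "MD" & fp$roi == "Right-Thalamus", "mean_PD"],
               1.271e-3)
  expect_equal(fp[fp$measure == "MD" & fp$roi == "Right-Thalamus", "sd_PD"],
               1.1e-4)
  des <- default_cohort_design()
  expect_equal(des$n_per_group, c(HC = 54L, PD = 65L, MSA = 31L))
})

test_that("generator is deterministic, degenerate at SD 0, and respects invariants", {
  a <- simulate_nos_cohort(n_per_group = c(HC = 5, PD = 5, MSA = 5), seed = 406)
  b <- simulate_nos_cohort(n_per_group = c(HC = 5, PD = 5, MSA = 5), seed = 406)
  expect_identical(a, b)
  expect_true(all(a$matrices >= 0))
  for (k in 1:15) {
    m <- a$matrices[, , k]
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
  }
  # SD = 0 everywhere: every subject equals its group mean matrix
  p0 <- nos_group_params()
  p0[grep("^sd_", names(p0))] <- 0
  c0 <- simulate_nos_cohort(p0, n_per_group = c(HC = 3, PD = 3, MSA = 3),
                            null_sd = 0, seed = 1)
  E <- cohort_edges(c0)
  for (g in c("HC", "PD", "MSA")) {
    rows <- E[c0$subjects$group == g, ]
    expect_equal(max(apply(rows, 2, function(x) diff(range(x)))), 0)
    expect_equal(unname(rows[1, p0$edge]), p0[[paste0("mean_", g)]])
  }
  expect_error(simulate_nos_cohort(n_per_group = c(HC = 1, PD = 5, MSA = 5)),
               "at least 2")
})

test_that("default gender split reproduces the study counts and has no edge effect", {
  coh <- simulate_nos_cohort(seed = 407)
  males <- tapply(coh$subjects$gender, coh$subjects$group, sum)
  expect_equal(males[["HC"]], 26)
  expect_equal(males[["PD"]], 48)
  expect_equal(males[["MSA"]], 19)
  # with a nonzero gender effect, male means shift on null edges
  eff <- simulate_nos_cohort(n_per_group = c(HC = 400, PD = 400, MSA = 400),
                             gender_effect = 2, seed = 408)
  E <- cohort_edges(eff)
  null_edge <- setdiff(seq_len(153), nos_group_params()$edge)[1]
  d <- mean(E[eff$subjects$gender == 1, null_edge]) -
    mean(E[eff$subjects$gender == 0, null_edge])
  expect_gt(d, 0.25e6)  # 2 SD shift, SE ~ 0.25e6/sqrt(300)
})

test_that("large-n empirical moments match the truncated-normal targets", {
  p <- nos_group_params()
  coh <- simulate_nos_cohort(p, n_per_group = c(HC = 10000, PD = 10000, MSA = 10000),
                             seed = 409)
  E <- cohort_edges(coh)
  for (g in c("HC", "PD", "MSA")) {
    X <- E[coh$subjects$group == g, p$edge]
    mu <- p[[paste0("mean_", g)]]
    sg <- p[[paste0("sd_", g)]]
    target <- mapply(function(m, s) subconn:::truncnorm_mean(m, s, 0), mu, sg)
    se <- sg / sqrt(10000)
    expect_true(all(abs(colMeans(X) - target) < 3.3 * se))
  }
  # KS distance to the truncated target < 0.02 on the strongest and weakest edge
  msa <- E[coh$subjects$group == "MSA", ]
  for (k in c(which.max(p$mean_MSA), which.min(p$mean_MSA))) {
    x <- sort(msa[, p$edge[k]])
    m <- p$mean_MSA[k]; s <- p$sd_MSA[k]
    p0 <- pnorm(0, m, s)
    cdf <- (pnorm(x, m, s) - p0) / (1 - p0)
    ks <- max(abs(cdf - seq_along(x) / length(x)),
              abs(cdf - (seq_along(x) - 1) / length(x)))
    expect_lt(ks, 0.02)
  }
})

test_that("feature-table generator mirrors the cohort generator contracts", {
  subj <- simulate_nos_cohort(n_per_group = c(HC = 4, PD = 4, MSA = 4),
                              seed = 410)$subjects
  a <- simulate_feature_tables(subj, seed = 411)
  b <- simulate_feature_tables(subj, seed = 411)
  expect_identical(a, b)
  expect_named(a, c("FA", "MD"))
  expect_true(all(a$FA >= 0 & a$FA <= 1))
  expect_true(all(a$MD >= 0))
  # SD = 0 -> constant per group
  fp0 <- feature_group_params()
  fp0[grep("^sd_", names(fp0))] <- 0
  c0 <- simulate_feature_tables(subj, fp0,
                                defaults = list(FA = c(0.4, 0), MD = c(1e-3, 0)),
                                seed = 1)
  for (g in unique(subj$group)) {
    rows <- c0$FA[subj$group == g, ]
    expect_equal(max(apply(rows, 2, function(x) diff(range(x)))), 0)
  }
  # large-n SDs within 5% of specified
  subj_big <- data.frame(id = sprintf("S%04d", 1:8000),
                         group = rep(c("HC", "PD", "MSA"), length.out = 8000),
                         gender = 0L)
  big <- simulate_feature_tables(subj_big, seed = 412)
  fp <- feature_group_params()
  for (g in c("HC", "MSA")) {
    fa <- fp[fp$measure == "FA", ]
    emp <- apply(big$FA[subj_big$group == g, fa$roi], 2, sd)
    expect_true(all(abs(emp / fa[[paste0("sd_", g)]] - 1) < 0.05))
  }
})
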