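# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths (loops instead of matrix algebra, BFS instead
# of union-find) so agreement is informative.

# Element-wise loop symmetrization.
oracle_symmetrize <- function(raw) {
  n <- nrow(raw)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) out[i, j] <- raw[i, j] + raw[j, i]
  }
  out
}

# Per-edge extension at threshold h by breadth-first search over nodes.
oracle_extension <- function(stat_matrix, h) {
  n <- nrow(stat_matrix)
  adj <- stat_matrix >= h
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(adj[u, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (adj[i, j]) {
      k <- comp[i]
      # edges within component k
      cnt <- 0L
      for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        if (adj[a, b] && comp[a] == k) cnt <- cnt + 1L
      }
      out[i, j] <- out[j, i] <- cnt
    }
  }
  out
}

# Per-edge enhancement rebuilt from scratch at every threshold via the BFS
# extension oracle.
oracle_tfce <- function(stat_matrix, E, H, n_steps, h_max = max(stat_matrix)) {
  n <- nrow(stat_matrix)
  score <- matrix(0, n, n)
  if (h_max <= 0) return(score)
  dh <- h_max / n_steps
  for (s in seq_len(n_steps)) {
    h <- s * dh
    heff <- h - 1e-12 * h_max  # same closed-threshold tolerance as the package
    ext <- oracle_extension(stat_matrix, heff)
    score <- score + (ext^E) * (h^H) * dh * (stat_matrix >= heff)
  }
  score
}

# Partial F via explicit lm() fits (residual-sum-of-squares oracle).
oracle_glm_f <- function(y, group, covariates = NULL) {
  df <- data.frame(y = y, group = factor(group))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  full <- stats::lm(y ~ ., data = df)
  red <- stats::lm(y ~ . - group, data = df)
  a <- stats::anova(red, full)
  a$F[2]
}

# Direct BH step-up evaluation (not p.adjust): largest k with
# p_(k) <= k q / m rejects the k smallest p-values.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ok <- which(p[ord] <= seq_len(m) * q / m)
  k <- if (length(ok)) max(ok) else 0L
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# Random symmetric zero-diagonal nonnegative atlas matrix.
random_sym_matrix <- function(scale = 10) {
  v <- stats::runif(n_atlas_edges(), 0, scale)
  edge_unflatten(v)
}

# Tiny cohort with given per-group edge values (n x 153 matrices by group).
cohort_from_edges <- function(edge_rows, groups, gender = NULL) {
  n <- nrow(edge_rows)
  if (is.null(gender)) gender <- rep_len(c(0L, 1L), n)
  arr <- array(0, c(18, 18, n))
  for (k in seq_len(n)) arr[, , k] <- edge_unflatten(edge_rows[k, ])
  nos_cohort(arr, data.frame(id = sprintf("S%03d", seq_len(n)),
                             group = groups, gender = gender,
                             stringsAsFactors = FALSE))
}

# Null three-group parameter table: HC parameters copied to all groups.
null_nos_params <- function() {
  p <- nos_group_params()
  for (g in c("PD", "MSA")) {
    p[[paste0("mean_", g)]] <- p$mean_HC
    p[[paste0("sd_", g)]] <- p$sd_HC
  }
  p
}

seeded_edge_names <- function() edge_index()$name[nos_group_params()$edge]

# Small two-group cohort builder: `k_sep` edges separated by `d` SDs, the
# rest exchangeable noise.
two_group_cohort <- function(n_per = 12, k_sep = 1, d = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  E <- matrix(rnorm(n * 153, 10, 1), n, 153) + 20
  if (k_sep > 0 && d != 0) {
    E[(n_per + 1):n, seq_len(k_sep)] <- E[(n_per + 1):n, seq_len(k_sep)] + d
  }
  cohort_from_edges(E, groups = rep(c("MSA", "PD"), each = n_per),
                    gender = rep_len(c(0L, 1L), n))
}
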