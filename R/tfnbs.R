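#' Configuration for threshold-free network-based statistics
#'
#' @param e_exponent extension exponent E applied to the component edge count
#'   (default 0.5).
#' @param h_exponent height exponent H applied to the threshold (default 3).
#' @param n_steps number of equally spaced thresholds from 0 (exclusive) to
#'   the grid maximum (default 100).
#' @param n_perm number of label permutations for inference (default 10000).
#' @param fdr_q FDR level defining the significant edge set (default 0.05).
#' @param grid_max `"adaptive"` (grid runs to each statistic matrix's own
#'   maximum, recomputed per permutation) or a fixed positive number shared
#'   by observed and null matrices.
#' @param seed optional integer seed for the permutation stream.
#' @return List of class `tfnbs_config`.
#' @export
tfnbs_config <- function(e_exponent = 0.5, h_exponent = 3, n_steps = 100,
                         n_perm = 10000, fdr_q = 0.05,
                         grid_max = "adaptive", seed = NULL) {
  stopifnot(e_exponent >= 0, h_exponent >= 0, n_steps >= 1, n_perm >= 1,
            fdr_q > 0, fdr_q < 1)
  if (!identical(grid_max, "adaptive")) {
    stopifnot(is.numeric(grid_max), grid_max > 0)
  }
  structure(list(e_exponent = e_exponent, h_exponent = h_exponent,
                 n_steps = n_steps, n_perm = n_perm, fdr_q = fdr_q,
                 grid_max = grid_max, seed = seed),
            class = "tfnbs_config")
}

#' Suprathreshold extension of each edge
#'
#' At threshold `h`, edges whose statistic is at least `h` (closed threshold)
#' form a graph over the atlas nodes; the extension of a suprathreshold edge
#' is the number of edges in its connected component, and 0 for
#' sub-threshold edges. This is the component-size notion of network-based
#' statistics, evaluated at a single threshold.
#'
#' @param stat_matrix symmetric nonnegative matrix of edge statistics.
#' @param h positive threshold.
#' @return Matrix of the same shape with each edge's extension e(h).
#' @export
suprathreshold_extension <- function(stat_matrix, h) {
  stopifnot(h > 0)
  n <- nrow(stat_matrix)
  ei <- edge_index(rownames(stat_matrix) %||% as.character(seq_len(n)))
  s <- stat_matrix[upper.tri(stat_matrix)]
  keep <- s >= h
  ext <- numeric(length(s))
  if (any(keep)) {
    g <- igraph::graph_from_edgelist(cbind(ei$i[keep], ei$j[keep]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    edge_comp <- comp[ei$i[keep]]
    ext[keep] <- as.numeric(table(edge_comp)[as.character(edge_comp)])
  }
  out <- matrix(0, n, n, dimnames = dimnames(stat_matrix))
  out[upper.tri(out)] <- ext
  out + t(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' TFCE-style enhancement of an edge-wise statistic matrix
#'
#' Replaces each edge's raw statistic by the threshold-free score
#' \deqn{\mathrm{score}(e) = \sum_h e_h(e)^E \, h^H \, \Delta h,}
#' summing over an equally spaced threshold grid, where \eqn{e_h(e)} is the
#' edge count of the suprathreshold connected component containing `e` at
#' threshold `h`. Effects that are both strong (height) and topologically
#' clustered (extension) are amplified; isolated weak effects are not.
#'
#' @param stat_matrix symmetric nonnegative matrix of edge statistics (or an
#'   edge vector of length 153).
#' @param config a [tfnbs_config()].
#' @return Symmetric matrix of enhanced scores (zero where the raw statistic
#'   is zero); if `stat_matrix` was a vector, an edge vector.
#' @export
tfce_enhance <- function(stat_matrix, config = tfnbs_config()) {
  vec_in <- !is.matrix(stat_matrix)
  s <- if (vec_in) as.numeric(stat_matrix)
       else stat_matrix[upper.tri(stat_matrix)]
  if (any(s < 0)) stop("edge statistics must be nonnegative")
  n <- if (vec_in) (1 + sqrt(1 + 8 * length(s))) / 2 else nrow(stat_matrix)
  ei <- edge_index(as.character(seq_len(n)))
  h_max <- if (identical(config$grid_max, "adaptive")) max(s) else config$grid_max
  scores <- tfce_edge_scores_cpp(s, ei$i - 1L, ei$j - 1L, as.integer(n),
                                 config$e_exponent, config$h_exponent,
                                 as.integer(config$n_steps), h_max)
  if (vec_in) {
    names(scores) <- names(stat_matrix)
    return(scores)
  }
  out <- matrix(0, n, n, dimnames = dimnames(stat_matrix))
  out[upper.tri(out)] <- scores
  out + t(out)
}

#' Threshold-free network-based statistics with permutation inference
#'
#' The omnibus group test on a connectome cohort: per edge, a
#' covariate-adjusted GLM F statistic for the group factor; the F matrix is
#' TFCE-enhanced over graph components; a null distribution of enhanced
#' scores is built by permuting group labels (covariates stay attached to
#' subjects) and re-running the identical enhancement (including the grid
#' policy); each edge's p-value is \eqn{(b+1)/(m+1)} against its own null
#' scores; BH-FDR at `fdr_q` defines the significant subnetwork.
#'
#' Edges failing the detection filter are excluded from testing entirely.
#'
#' @param cohort a [nos_cohort()].
#' @param config a [tfnbs_config()].
#' @param covariates subject-table columns to adjust for (default
#'   `"gender"`; `NULL` for none).
#' @param min_fraction detection-filter fraction (see
#'   [apply_detection_filter()]).
#' @return Object of class `tfnbs_result`: list with `f_matrix`,
#'   `score_matrix`, `stats` (tidy per-edge data.frame with `f`, `score`,
#'   `p_perm`, `p_fdr`, `significant`), `significant` (edge names), `mask`,
#'   `n_tested`, `config`.
#' @export
tfnbs_inference <- function(cohort, config = tfnbs_config(),
                            covariates = "gender", min_fraction = 0.5) {
  stopifnot(inherits(cohort, "nos_cohort"))
  if (length(unique(cohort$subjects$group)) < 2) stop("need at least 2 groups")
  if (!is.null(config$seed)) set.seed(config$seed)
  mask <- apply_detection_filter(cohort, min_fraction)
  if (!any(mask)) stop("no edges survive the detection filter")
  E <- cohort_edges(cohort)
  Y <- E[, mask, drop = FALSE]
  if (all(Y == 0)) stop("all detected edges are zero")
  group <- factor(cohort$subjects$group)
  covs <- if (is.null(covariates)) NULL else
    cohort$subjects[, covariates, drop = FALSE]
  labels <- cohort$labels
  ne <- n_atlas_edges(labels)
  ei <- edge_index(labels)

  enhance_vec <- function(fv) {
    full <- numeric(ne)
    full[mask] <- fv
    h_max <- if (identical(config$grid_max, "adaptive")) max(full) else config$grid_max
    tfce_edge_scores_cpp(full, ei$i - 1L, ei$j - 1L, length(labels),
                         config$e_exponent, config$h_exponent,
                         as.integer(config$n_steps), h_max)[mask]
  }

  d <- group_designs(group, covs)
  f_obs <- glm_f_matrix(Y, designs = d)
  score_obs <- enhance_vec(f_obs)

  b <- rep(0L, sum(mask))
  for (r in seq_len(config$n_perm)) {
    gp <- sample(group)
    dp <- group_designs(gp, covs, check_rank = FALSE)
    f_perm <- glm_f_matrix(Y, designs = dp)
    b <- b + (enhance_vec(f_perm) >= score_obs - 1e-12)
  }
  p_perm <- (b + 1) / (config$n_perm + 1)
  fdr <- bh_fdr(p_perm, config$fdr_q)

  stats <- data.frame(
    edge = which(mask),
    roi_a = ei$roi_a[mask], roi_b = ei$roi_b[mask],
    name = ei$name[mask],
    f = unname(f_obs), score = unname(score_obs),
    p_perm = p_perm, p_fdr = fdr$adjusted, significant = fdr$rejected,
    stringsAsFactors = FALSE
  )
  f_full <- numeric(ne); f_full[mask] <- f_obs
  s_full <- numeric(ne); s_full[mask] <- score_obs
  structure(
    list(
      f_matrix = edge_unflatten(f_full, labels),
      score_matrix = edge_unflatten(s_full, labels),
      stats = stats,
      significant = stats$name[stats$significant],
      mask = mask,
      n_tested = sum(mask),
      config = config
    ),
    class = "tfnbs_result"
  )
}

#' @export
print.tfnbs_result <- function(x, ...) {
  cat("TFNBS inference:", x$n_tested, "edges tested,",
      length(x$significant), "significant at FDR", x$config$fdr_q, "\n")
  if (length(x$significant)) {
    sig <- x$stats[x$stats$significant, c("roi_a", "roi_b", "f", "score", "p_fdr")]
    sig <- sig[order(sig$p_fdr, -sig$f), ]
    print(sig, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
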