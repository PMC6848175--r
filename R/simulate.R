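# Truncated-normal sampler by inverse CDF. sd == 0 gives a point mass at
# max(mean, floor). Returns n draws from N(mean, sd) conditioned on >= floor.
rtruncnorm_floor <- function(n, mean, sd, floor = 0) {
  if (sd < 0) stop("negative SD")
  if (sd == 0) return(rep(max(mean, floor), n))
  p0 <- stats::pnorm(floor, mean, sd)
  if (p0 >= 1) return(rep(floor, n))
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

# Mean of N(mean, sd) truncated below at `floor` (the generator's actual
# target mean; equals `mean` wherever the truncated mass is negligible).
truncnorm_mean <- function(mean, sd, floor = 0) {
  if (sd == 0) return(pmax(mean, floor))
  a <- (floor - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# Per-group gender vector: deterministic male/female counts from the split,
# scaled to n (largest-remainder rounding on the male count).
gender_codes <- function(n, split) {
  p_male <- split[["male"]] / sum(split)
  n_male <- round(n * p_male)
  c(rep(1L, n_male), rep(0L, n - n_male))
}

#' Simulate a streamline-count cohort
#'
#' Draws each subject's NOS value at each edge independently from a normal
#' distribution with that edge's group mean and SD, truncated below at
#' `floor` (streamline counts cannot be negative). Edges listed in `params`
#' carry group-specific parameters; all remaining edges share a
#' group-invariant null parameterization, so any group signal lives only on
#' the listed edges. Gender is assigned per group from the study's
#' male/female split and, by default, has no effect on edges — covariate
#' adjustment can thus be validated under the null; set `gender_effect` to a
#' nonzero number of SDs to simulate a genuine confound.
#'
#' @param params per-edge group parameters, as from [nos_group_params()].
#' @param n_per_group named integer vector of group sizes
#'   (default `c(HC = 54, PD = 65, MSA = 31)`).
#' @param gender_split named list of `c(male, female)` counts per group
#'   (default: the study's split; scaled proportionally for other sizes).
#' @param null_mean,null_sd parameters shared by all unlisted edges,
#'   identical across groups (defaults 1e6 and 0.25e6 streamlines, the
#'   magnitude of the listed edges).
#' @param floor truncation floor (default 0).
#' @param gender_effect additive shift, in units of the edge SD, applied to
#'   male subjects' edge means (default 0).
#' @param equicorrelation optional common correlation between edges within a
#'   subject (default 0 = independent). When nonzero, sampling uses
#'   correlated normals censored at the floor instead of exact truncation.
#' @param seed optional integer seed (local to this call).
#' @return A [nos_cohort()].
#' @export
simulate_nos_cohort <- function(params = nos_group_params(),
                                n_per_group = default_cohort_design()$n_per_group,
                                gender_split = default_cohort_design()$gender_split,
                                null_mean = 1e6, null_sd = 0.25e6,
                                floor = 0, gender_effect = 0,
                                equicorrelation = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- names(n_per_group)
  if (is.null(groups)) stop("n_per_group must be named by group")
  if (any(n_per_group < 2)) stop("need at least 2 subjects per group")
  if (null_sd < 0 || any(params[grep("^sd_", names(params))] < 0))
    stop("negative SD in parameters")
  if (!(equicorrelation >= 0 && equicorrelation < 1))
    stop("equicorrelation must be in [0, 1)")
  ne <- n_atlas_edges()
  # per-group mean/sd over all 153 edges
  mu <- sapply(groups, function(g) {
    v <- rep(null_mean, ne); v[params$edge] <- params[[paste0("mean_", g)]]; v
  })
  sg <- sapply(groups, function(g) {
    v <- rep(null_sd, ne); v[params$edge] <- params[[paste0("sd_", g)]]; v
  })
  subj <- list(); mats <- list()
  for (g in groups) {
    n <- n_per_group[[g]]
    split <- if (!is.null(gender_split[[g]])) gender_split[[g]]
             else c(male = 1L, female = 1L)
    gender <- gender_codes(n, split)
    X <- matrix(0, n, ne)
    for (e in seq_len(ne)) {
      m_e <- mu[e, g] + gender_effect * sg[e, g] * gender
      if (equicorrelation == 0) {
        # exact truncated-normal sampling, vectorized over the gender shift
        sd_e <- sg[e, g]
        if (sd_e == 0) {
          X[, e] <- pmax(m_e, floor)
        } else {
          p0 <- stats::pnorm(floor, m_e, sd_e)
          X[, e] <- stats::qnorm(p0 + stats::runif(n) * (1 - p0), m_e, sd_e)
        }
      } else {
        X[, e] <- m_e  # filled below with correlated draws
      }
    }
    if (equicorrelation > 0) {
      z_subj <- stats::rnorm(n)
      Z <- sqrt(equicorrelation) * z_subj +
        sqrt(1 - equicorrelation) * matrix(stats::rnorm(n * ne), n, ne)
      X <- pmax(X + Z * matrix(sg[, g], n, ne, byrow = TRUE), floor)
    }
    ids <- sprintf("%s%03d", g, seq_len(n))
    subj[[g]] <- data.frame(id = ids, group = g, gender = gender,
                            stringsAsFactors = FALSE)
    mats[[g]] <- X
  }
  subjects <- do.call(rbind, subj)
  rownames(subjects) <- NULL
  X <- do.call(rbind, mats)
  arr <- array(0, c(18, 18, nrow(subjects)))
  for (k in seq_len(nrow(subjects))) arr[, , k] <- edge_unflatten(X[k, ])
  nos_cohort(arr, subjects)
}

#' Simulate per-ROI feature tables
#'
#' Generates per-subject, per-ROI scalar features (FA, MD) from group
#' normals, mirroring [simulate_nos_cohort()]: ROIs listed in `params` carry
#' group-specific means/SDs, all others a group-invariant default per
#' measure. FA is truncated to [0, 1]; MD below at 0.
#'
#' @param subjects subject table (`id`, `group`, `gender`), e.g. from a
#'   simulated cohort, so features align with its matrices.
#' @param params per-ROI group parameters, as from [feature_group_params()].
#' @param defaults named list of `c(mean, sd)` per measure for ROIs without
#'   published rows.
#' @param seed optional integer seed (local to this call).
#' @return Named list of `n_subjects x 18` matrices, one per measure.
#' @export
simulate_feature_tables <- function(subjects, params = feature_group_params(),
                                    defaults = list(FA = c(0.40, 0.03),
                                                    MD = c(1.0e-3, 1.0e-4)),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- subcortical_atlas()
  out <- list()
  for (meas in unique(params$measure)) {
    pm <- params[params$measure == meas, , drop = FALSE]
    def <- defaults[[meas]]
    if (is.null(def)) stop("no default parameters for measure ", meas)
    ft <- matrix(0, nrow(subjects), length(labels),
                 dimnames = list(subjects$id, labels))
    for (r in seq_along(labels)) {
      row <- pm[pm$roi == labels[r], , drop = FALSE]
      for (g in unique(subjects$group)) {
        idx <- subjects$group == g
        if (nrow(row) == 1) {
          m <- row[[paste0("mean_", g)]]; s <- row[[paste0("sd_", g)]]
        } else {
          m <- def[1]; s <- def[2]
        }
        ft[idx, r] <- rtruncnorm_floor(sum(idx), m, s, floor = 0)
      }
    }
    if (meas == "FA") ft <- pmin(ft, 1)
    out[[meas]] <- ft
  }
  out
}
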