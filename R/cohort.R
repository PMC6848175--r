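#' Symmetrize a directed streamline-count matrix
#'
#' Probabilistic tractography counts streamlines seeded in region i that reach
#' region j and vice versa; the undirected connectome entry is their sum,
#' `out[i, j] = raw[i, j] + raw[j, i]` for `i != j`, with a zero diagonal.
#'
#' @param raw square nonnegative count matrix with zero diagonal (directed
#'   counts; need not be symmetric).
#' @param labels atlas labels used to validate/assign dimnames.
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
symmetrize_counts <- function(raw, labels = subcortical_atlas()) {
  n <- length(labels)
  if (!is.matrix(raw) || nrow(raw) != n || ncol(raw) != n)
    stop("expected a ", n, "x", n, " matrix of directed counts")
  if (anyNA(raw) || any(raw < 0))
    stop("directed counts must be nonnegative and complete")
  if (any(diag(raw) != 0))
    stop("directed counts must have a zero diagonal")
  out <- raw + t(raw)
  diag(out) <- 0
  dimnames(out) <- list(labels, labels)
  out
}

#' Construct a cohort of connectomes
#'
#' Bundles per-subject symmetric NOS (number-of-streamlines) matrices with a
#' subject table and optional per-ROI feature tables (e.g. FA, MD, volume).
#'
#' @param matrices 3-D array `n_roi x n_roi x n_subjects` (or list of
#'   matrices), each slice symmetric, nonnegative, zero-diagonal.
#' @param subjects data.frame with at least columns `id`, `group`, `gender`
#'   (0/1); rows aligned with the third array dimension.
#' @param features optional named list of numeric matrices
#'   (`n_subjects x n_roi`) of per-ROI scalar features.
#' @param labels atlas labels.
#' @return Object of class `nos_cohort`.
#' @export
nos_cohort <- function(matrices, subjects, features = list(),
                       labels = subcortical_atlas()) {
  if (is.list(matrices) && !is.array(matrices)) {
    matrices <- simplify2array(matrices)
  }
  n <- length(labels)
  if (length(dim(matrices)) != 3L || dim(matrices)[1] != n || dim(matrices)[2] != n)
    stop("matrices must be an ", n, "x", n, "xN array")
  if (nrow(subjects) == 0L) stop("cohort is empty")
  if (dim(matrices)[3] != nrow(subjects))
    stop("number of matrices (", dim(matrices)[3],
         ") does not match number of subjects (", nrow(subjects), ")")
  req <- c("id", "group", "gender")
  miss <- setdiff(req, names(subjects))
  if (length(miss)) stop("subject table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(subjects$id)) stop("duplicated subject ids")
  subjects$id <- as.character(subjects$id)
  subjects$group <- as.character(subjects$group)
  for (k in seq_len(dim(matrices)[3])) {
    m <- matrices[, , k]
    if (anyNA(m) || any(m < 0))
      stop("matrix for subject ", subjects$id[k], " has negative or missing values")
    if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
      stop("matrix for subject ", subjects$id[k], " is not symmetric")
    if (any(diag(m) != 0))
      stop("matrix for subject ", subjects$id[k], " has a nonzero diagonal")
  }
  dimnames(matrices) <- list(labels, labels, subjects$id)
  if (length(features)) {
    if (is.null(names(features)) || any(names(features) == ""))
      stop("feature tables must be named")
    for (nm in names(features)) {
      ft <- features[[nm]]
      if (!is.matrix(ft) || nrow(ft) != nrow(subjects) || ncol(ft) != n)
        stop("feature table '", nm, "' must be n_subjects x n_roi")
      dimnames(ft) <- list(subjects$id, labels)
      features[[nm]] <- ft
    }
  }
  structure(
    list(matrices = matrices, subjects = subjects,
         features = features, labels = labels),
    class = "nos_cohort"
  )
}

#' @export
print.nos_cohort <- function(x, ...) {
  cat("Subcortical connectome cohort:", nrow(x$subjects), "subjects,",
      length(x$labels), "ROIs,", n_atlas_edges(x$labels), "possible edges\n")
  print(table(x$subjects$group))
  if (length(x$features))
    cat("Feature tables:", paste(names(x$features), collapse = ", "), "\n")
  invisible(x)
}

#' Subjects-by-edges matrix of a cohort
#'
#' @param cohort a [nos_cohort()].
#' @return Numeric matrix `n_subjects x n_edges`, columns named by edge.
#' @export
cohort_edges <- function(cohort) {
  stopifnot(inherits(cohort, "nos_cohort"))
  nsub <- nrow(cohort$subjects)
  ne <- n_atlas_edges(cohort$labels)
  out <- matrix(0, nsub, ne,
                dimnames = list(cohort$subjects$id, edge_index(cohort$labels)$name))
  ut <- upper.tri(matrix(0, length(cohort$labels), length(cohort$labels)))
  for (k in seq_len(nsub)) out[k, ] <- cohort$matrices[, , k][ut]
  out
}

#' Subset a cohort by subjects
#'
#' @param cohort a [nos_cohort()].
#' @param keep logical or integer index over subjects, or character ids.
#' @return A [nos_cohort()] restricted to the selected subjects.
#' @export
subset_cohort <- function(cohort, keep) {
  stopifnot(inherits(cohort, "nos_cohort"))
  if (is.character(keep)) keep <- match(keep, cohort$subjects$id)
  subjects <- cohort$subjects[keep, , drop = FALSE]
  rownames(subjects) <- NULL
  feats <- lapply(cohort$features, function(ft) ft[keep, , drop = FALSE])
  nos_cohort(cohort$matrices[, , keep, drop = FALSE], subjects, feats,
             cohort$labels)
}

#' Detection filter over cohort edges
#'
#' Keeps an edge only if its streamline count is strictly positive in at
#' least `ceiling(min_fraction * n_subjects)` subjects, pooled across groups.
#' Spurious connections reconstructed in only a few subjects are thereby
#' excluded from all downstream testing.
#'
#' @param cohort a [nos_cohort()].
#' @param min_fraction minimum fraction of subjects in which an edge must be
#'   detected (default 0.5).
#' @return Named logical vector over the 153 edges (`TRUE` = kept).
#' @export
apply_detection_filter <- function(cohort, min_fraction = 0.5) {
  stopifnot(inherits(cohort, "nos_cohort"))
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must be in (0, 1]")
  E <- cohort_edges(cohort)
  need <- ceiling(min_fraction * nrow(E))
  colSums(E > 0) >= need
}

#' Mean z-scored streamline count over an edge set
#'
#' Each edge is standardized across all subjects pooled (sample mean 0,
#' sample SD 1); the summary for a subject is the mean z over the edge set.
#' Used to display a single global connectivity score over, e.g., the
#' significant subnetwork.
#'
#' @param cohort a [nos_cohort()].
#' @param edges edge positions (integer), names, or logical mask.
#' @return Named numeric vector, one summary value per subject.
#' @export
edge_zscore_summary <- function(cohort, edges) {
  stopifnot(inherits(cohort, "nos_cohort"))
  E <- cohort_edges(cohort)
  if (is.logical(edges)) edges <- which(edges)
  if (is.character(edges)) edges <- match(edges, colnames(E))
  if (length(edges) == 0L || anyNA(edges)) stop("empty or unknown edge set")
  X <- E[, edges, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " zero-variance edge(s) from z-score summary")
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) == 0L) stop("all requested edges have zero variance")
  }
  Z <- scale(X)
  out <- rowMeans(Z)
  names(out) <- cohort$subjects$id
  out
}

#' Write a cohort to delimited text files
#'
#' Writes `subjects.csv`, one `matrices/<id>.csv` per subject (with ROI label
#' headers), a `manifest.csv` mapping subject id to matrix file, and one
#' `features_<name>.csv` per feature table.
#'
#' @param cohort a [nos_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nos_cohort"))
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  files <- file.path("matrices", paste0(cohort$subjects$id, ".csv"))
  for (k in seq_len(nrow(cohort$subjects))) {
    m <- cohort$matrices[, , k]
    utils::write.csv(m, file.path(dir, files[k]), row.names = TRUE)
  }
  utils::write.csv(
    data.frame(id = cohort$subjects$id, file = files, stringsAsFactors = FALSE),
    file.path(dir, "manifest.csv"), row.names = FALSE
  )
  for (nm in names(cohort$features)) {
    utils::write.csv(cohort$features[[nm]],
                     file.path(dir, paste0("features_", nm, ".csv")),
                     row.names = TRUE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Matrix files are validated against the atlas by label, not by position:
#' a file whose header disagrees with the atlas is rejected with an error
#' naming the file.
#'
#' @param dir directory containing `manifest.csv` and `subjects.csv`.
#' @param labels atlas labels.
#' @return A [nos_cohort()].
#' @export
read_cohort <- function(dir, labels = subcortical_atlas()) {
  man_path <- file.path(dir, "manifest.csv")
  subj_path <- file.path(dir, "subjects.csv")
  if (!file.exists(man_path)) stop("no manifest.csv found in ", dir)
  if (!file.exists(subj_path)) stop("no subjects.csv found in ", dir)
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  if (!all(c("id", "file") %in% names(manifest)))
    stop("manifest.csv must have columns id, file")
  subjects <- utils::read.csv(subj_path, stringsAsFactors = FALSE)
  ord <- match(subjects$id, manifest$id)
  if (anyNA(ord))
    stop("subjects.csv lists id(s) absent from manifest.csv: ",
         paste(subjects$id[is.na(ord)], collapse = ", "))
  n <- length(labels)
  mats <- array(0, c(n, n, nrow(subjects)))
  for (k in seq_len(nrow(subjects))) {
    path <- file.path(dir, manifest$file[ord[k]])
    if (!file.exists(path)) stop("matrix file missing: ", path)
    m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
    if (!identical(rownames(m), labels) || !identical(colnames(m), labels))
      stop("ROI labels in ", path, " do not match the atlas")
    mats[, , k] <- m
  }
  features <- list()
  for (fp in list.files(dir, pattern = "^features_.*\\.csv$", full.names = TRUE)) {
    nm <- sub("^features_(.*)\\.csv$", "\\1", basename(fp))
    ft <- as.matrix(utils::read.csv(fp, row.names = 1, check.names = FALSE))
    if (!identical(colnames(ft), labels))
      stop("ROI labels in ", fp, " do not match the atlas")
    features[[nm]] <- ft[subjects$id, , drop = FALSE]
  }
  nos_cohort(mats, subjects, features, labels)
}
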