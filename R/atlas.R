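#' Subcortical ROI atlas
#'
#' The 18 subcortical regions used as network nodes, in canonical order.
#' The order follows the FreeSurfer `aseg` listing (cerebellar white matter,
#' thalamus, caudate, putamen, pallidum, hippocampus, amygdala, accumbens
#' area, ventral diencephalon), left hemisphere first, then right. This
#' order defines the edge indexing used throughout the package, so matrices
#' written by one tool remain portable to another.
#'
#' @return Character vector of 18 unique ROI labels.
#' @export
#' @examples
#' subcortical_atlas()
subcortical_atlas <- function() {
  structures <- c(
    "Cerebellum-White-Matter", "Thalamus", "Caudate", "Putamen",
    "Pallidum", "Hippocampus", "Amygdala", "Accumbens-area", "VentralDC"
  )
  c(paste0("Left-", structures), paste0("Right-", structures))
}

#' Number of undirected edges in the atlas graph
#'
#' @param labels atlas labels (default [subcortical_atlas()]).
#' @return Integer, `n * (n - 1) / 2` (153 for the default atlas).
#' @export
n_atlas_edges <- function(labels = subcortical_atlas()) {
  n <- length(labels)
  as.integer(n * (n - 1L) / 2L)
}

#' Edge index for the atlas
#'
#' Bijective mapping between unordered ROI pairs and flat edge positions.
#' Edges are enumerated in upper-triangle column-major order, i.e. the order
#' produced by `m[upper.tri(m)]`, so position 1 is the pair of the first two
#' atlas labels.
#'
#' @param labels atlas labels (default [subcortical_atlas()]).
#' @return A data.frame with columns `edge` (1-based position), `i`, `j`
#'   (node indices, `i < j`), `roi_a`, `roi_b` (labels) and `name`
#'   (`"roi_a|roi_b"`).
#' @export
edge_index <- function(labels = subcortical_atlas()) {
  n <- length(labels)
  ut <- upper.tri(matrix(0, n, n))
  i <- row(ut)[ut]
  j <- col(ut)[ut]
  data.frame(
    edge = seq_along(i),
    i = i, j = j,
    roi_a = labels[i], roi_b = labels[j],
    name = paste(labels[i], labels[j], sep = "|"),
    stringsAsFactors = FALSE
  )
}

#' Look up the flat position of an ROI pair
#'
#' Order-independent: `edge_position(a, b)` equals `edge_position(b, a)`.
#'
#' @param roi_a,roi_b ROI labels or 1-based node indices.
#' @param labels atlas labels.
#' @return Integer edge position in `1..n_atlas_edges()`.
#' @export
edge_position <- function(roi_a, roi_b, labels = subcortical_atlas()) {
  idx <- function(x) {
    if (is.character(x)) {
      m <- match(x, labels)
      if (anyNA(m)) stop("unknown ROI label: ", paste(x[is.na(m)], collapse = ", "))
      m
    } else as.integer(x)
  }
  a <- idx(roi_a); b <- idx(roi_b)
  if (any(a == b)) stop("self-pairs have no edge position")
  lo <- pmin(a, b); hi <- pmax(a, b)
  # column-major upper triangle: edges above column `hi` come first
  as.integer((hi - 1L) * (hi - 2L) / 2L + lo)
}

#' Flatten a symmetric matrix to its upper-triangle edge vector
#'
#' @param m square symmetric numeric matrix over the atlas.
#' @param labels atlas labels; if `m` has dimnames they are checked.
#' @return Numeric vector of length `n_atlas_edges(labels)`, named by edge.
#' @export
edge_flatten <- function(m, labels = subcortical_atlas()) {
  n <- length(labels)
  if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
    stop("expected a ", n, "x", n, " matrix")
  if (!is.null(rownames(m)) && !identical(rownames(m), labels))
    stop("matrix row labels do not match the atlas")
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    stop("matrix is not symmetric")
  v <- m[upper.tri(m)]
  names(v) <- edge_index(labels)$name
  v
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [edge_flatten()]: `edge_unflatten(edge_flatten(m))` returns `m`
#' for any symmetric zero-diagonal matrix.
#'
#' @param v numeric vector of length `n_atlas_edges(labels)`.
#' @param labels atlas labels.
#' @param diag value placed on the diagonal (default 0).
#' @return Symmetric matrix with atlas dimnames.
#' @export
edge_unflatten <- function(v, labels = subcortical_atlas(), diag = 0) {
  n <- length(labels)
  if (length(v) != n * (n - 1L) / 2L)
    stop("expected ", n * (n - 1L) / 2L, " edge values, got ", length(v))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag
  m
}
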