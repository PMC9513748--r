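#' Pairwise distances between fingerprints
#'
#' Full symmetric distance matrix between the rows of a spectrum matrix.
#' `euclidean` is the default metric used throughout the pipeline;
#' `one_minus_pearson` (1 minus the Pearson correlation of two spectra) is
#' the pluggable shape-sensitive alternative.
#'
#' @param X Numeric matrix, one spectrum per row.
#' @param metric `"euclidean"` or `"one_minus_pearson"`.
#' @return A `sers_distmat`: list with `ids` (rownames of `X`, or indices)
#'   and `values` (symmetric matrix, zero diagonal).
#' @export
pairwise_distances <- function(X, metric = c("euclidean", "one_minus_pearson")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("need at least one spectrum", call. = FALSE)
  values <- if (metric == "euclidean") {
    as.matrix(stats::dist(X, method = "euclidean"))
  } else {
    v <- 1 - stats::cor(t(X))
    diag(v) <- 0
    v
  }
  values <- (values + t(values)) / 2
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, metric = metric),
            class = "sers_distmat")
}

cross_distances <- function(A, B, metric = c("euclidean", "one_minus_pearson")) {
  metric <- match.arg(metric)
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("spectra differ in length", call. = FALSE)
  if (metric == "euclidean") {
    sa <- rowSums(A^2)
    sb <- rowSums(B^2)
    d2 <- outer(sa, sb, `+`) - 2 * tcrossprod(A, B)
    # the expansion cancels catastrophically for near-identical rows;
    # recompute those few entries directly
    tiny <- which(d2 < 1e-9 * max(sa, sb, .Machine$double.xmin),
                  arr.ind = TRUE)
    for (k in seq_len(nrow(tiny))) {
      i <- tiny[k, 1L]; j <- tiny[k, 2L]
      d2[i, j] <- sum((A[i, ] - B[j, ])^2)
    }
    sqrt(pmax(d2, 0))
  } else {
    1 - stats::cor(t(A), t(B))
  }
}

#' Nearest-neighbour distances from a query set to a reference set
#'
#' For each query fingerprint, the distance to its closest reference
#' fingerprint. Ties are broken by the lowest reference index (this affects
#' only the reported neighbour id, never the distance).
#'
#' @param query,reference Matrices with one spectrum per row and matching
#'   number of columns.
#' @param metric Distance metric, as in [pairwise_distances()].
#' @return Numeric vector of length `nrow(query)` with attribute
#'   `neighbor_index` (row index into `reference`).
#' @export
nearest_neighbor_distances <- function(query, reference,
                                       metric = c("euclidean",
                                                  "one_minus_pearson")) {
  metric <- match.arg(metric)
  if (is.null(dim(reference)) || nrow(reference) < 1L) {
    stop("reference set is empty", call. = FALSE)
  }
  D <- cross_distances(query, reference, metric)
  idx <- max.col(-D, ties.method = "first")
  d <- D[cbind(seq_len(nrow(D)), idx)]
  attr(d, "neighbor_index") <- idx
  d
}

#' Hierarchical clustering of fingerprints
#'
#' Agglomerative clustering on a precomputed distance matrix; a thin wrapper
#' around [stats::hclust()] restricted to the linkages whose merge heights
#' are meaningful for fingerprint subtyping.
#'
#' @param distmat A `sers_distmat` from [pairwise_distances()].
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An [stats::hclust] object whose labels are the spectrum ids.
#' @export
hcluster <- function(distmat, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(distmat, "sers_distmat"))
  if (length(distmat$ids) < 2L) {
    stop("need at least 2 spectra to cluster", call. = FALSE)
  }
  stats::hclust(stats::as.dist(distmat$values), method = linkage)
}

#' Cut a dendrogram into vesicle subtypes
#'
#' Subtypes are the connected components left after removing all merges above
#' `cut_height`.
#'
#' @param dendrogram An [stats::hclust] object from [hcluster()].
#' @param cut_height Non-negative cut height.
#' @return A `sers_subtypes`: list with `assignment` (named integer vector,
#'   spectrum id -> type id) and `members` (list of id vectors per type).
#' @export
assign_subtypes <- function(dendrogram, cut_height) {
  stopifnot(inherits(dendrogram, "hclust"), cut_height >= 0)
  if (!is.finite(cut_height)) cut_height <- max(dendrogram$height) + 1
  cl <- stats::cutree(dendrogram, h = cut_height)
  structure(list(assignment = cl,
                 members = split(names(cl), cl)),
            class = "sers_subtypes")
}

#' Data-driven dendrogram cut height
#'
#' Suggests a cut for type discovery as the midpoint of the largest gap in
#' the sorted merge heights. When distinct vesicle types are well separated,
#' within-type merges accumulate at small heights and between-type merges at
#' much larger ones; the widest gap separates the two regimes. This adapts to
#' the sampling density of the set being clustered, unlike a threshold
#' calibrated on a (usually denser) reference population.
#'
#' @param dendrogram An [stats::hclust] object from [hcluster()].
#' @return A cut height. With a single merge, half its height (each point
#'   keeps its own type only if the two points are far apart relative to 0).
#' @export
suggest_cut_height <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "hclust"))
  h <- sort(dendrogram$height)
  if (length(h) == 1L) return(h / 2)
  gaps <- diff(h)
  k <- which.max(gaps)
  (h[k] + h[k + 1L]) / 2
}

#' Common-versus-unique decision threshold from a control set
#'
#' The threshold tau that operationalizes "shares common spectral features
#' with the control group": the stated percentile of the leave-self-out
#' nearest-neighbour distances *within* the control set. A patient
#' fingerprint closer than tau to some control fingerprint is as close as
#' control fingerprints typically are to each other, and is treated as a
#' common (non-disease-specific) vesicle.
#'
#' @param control_X Matrix of control fingerprints (>= 2 rows).
#' @param percentile Percentile in (0, 100]; default 95 (100 gives the
#'   maximum leave-self-out NN distance).
#' @param metric Distance metric, as in [pairwise_distances()].
#' @return tau, a single non-negative number.
#' @export
derive_threshold <- function(control_X, percentile = 95,
                             metric = c("euclidean", "one_minus_pearson")) {
  metric <- match.arg(metric)
  control_X <- as.matrix(control_X)
  if (nrow(control_X) < 2L) {
    stop("need at least 2 control spectra", call. = FALSE)
  }
  if (percentile <= 0 || percentile > 100) {
    stop("percentile must lie in (0, 100]", call. = FALSE)
  }
  D <- pairwise_distances(control_X, metric)$values
  diag(D) <- Inf
  nn <- apply(D, 1L, min)
  unname(stats::quantile(nn, percentile / 100, type = 7))
}
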