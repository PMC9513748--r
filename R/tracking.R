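#' Cluster patient-unique spectra of one fluid into vesicle types
#'
#' Hierarchical clustering (average linkage by default) of the PP
#' fingerprints of one biofluid, cut at `cut_height`. A single spectrum forms
#' one singleton type; a cut at `Inf` yields one type.
#'
#' @param X PP fingerprint matrix for one fluid (>= 1 row).
#' @param ids Spectrum ids for the rows.
#' @param cut_height Dendrogram cut height, typically the control-derived
#'   tau from [derive_threshold()].
#' @param linkage Linkage method, see [hcluster()].
#' @param metric Distance metric, see [pairwise_distances()].
#' @return A `sers_type_set`: list with `members` (list of id vectors),
#'   `centroids` (k x p matrix), `X`, `ids`, `assignment`.
#' @export
cluster_pp_types <- function(X, ids, cut_height, linkage = "average",
                             metric = "euclidean") {
  X <- as.matrix(X)
  ids <- as.character(ids)
  stopifnot(nrow(X) == length(ids), nrow(X) >= 1L)
  rownames(X) <- ids
  if (nrow(X) == 1L) {
    assignment <- stats::setNames(1L, ids)
  } else {
    dend <- hcluster(pairwise_distances(X, metric), linkage)
    assignment <- assign_subtypes(dend, cut_height)$assignment
  }
  members <- split(ids, assignment)
  centroids <- do.call(rbind, lapply(members, function(m) {
    colMeans(X[m, , drop = FALSE])
  }))
  structure(list(members = members, centroids = centroids, X = X, ids = ids,
                 assignment = assignment, cut_height = cut_height),
            class = "sers_type_set")
}

#' Match patient-unique vesicle types across tissue, blood and saliva
#'
#' A tissue type matches a blood (resp. saliva) type when their centroids are
#' mutually nearest and at most `tau_track` apart; requiring mutual nearest
#' neighbours prevents chained many-to-one matches. A type is reported only
#' when it has a match in *both* other fluids, i.e. it exists across all
#' three conditions.
#'
#' @param types_tissue,types_blood,types_saliva `sers_type_set` objects from
#'   [cluster_pp_types()], on the same wavenumber grid.
#' @param tau_track Centroid distance threshold; the same control-calibrated
#'   tau family used for relabeling is the natural choice.
#' @param metric Distance metric for centroid comparison.
#' @return A `sers_tracking_result`: list of matched types, each with
#'   `type_id`, `members` (per-fluid id lists), `centroids` (per-fluid),
#'   `mean_spectrum` (mean over all member spectra of the three fluids) and
#'   `counts`.
#' @export
match_types_across_fluids <- function(types_tissue, types_blood,
                                      types_saliva, tau_track,
                                      metric = "euclidean") {
  sets <- list(tissue = types_tissue, blood = types_blood,
               saliva = types_saliva)
  empty <- vapply(sets, function(s) is.null(s) || length(s$members) == 0L,
                  logical(1))
  if (any(empty)) {
    warning("no PP types in fluid(s): ",
            paste(names(sets)[empty], collapse = ", "),
            "; no cross-fluid types can be matched")
    return(structure(list(types = list()), class = "sers_tracking_result"))
  }
  match_one <- function(A, B) {
    D <- cross_distances(A$centroids, B$centroids, metric)
    a_best <- max.col(-D, ties.method = "first")
    b_best <- max.col(-t(D), ties.method = "first")
    vapply(seq_len(nrow(D)), function(i) {
      j <- a_best[i]
      if (b_best[j] == i && D[i, j] <= tau_track) j else NA_integer_
    }, integer(1))
  }
  mb <- match_one(types_tissue, types_blood)
  ms <- match_one(types_tissue, types_saliva)
  keep <- which(!is.na(mb) & !is.na(ms))
  types <- lapply(seq_along(keep), function(q) {
    i <- keep[q]
    members <- list(tissue = types_tissue$members[[i]],
                    blood = types_blood$members[[mb[i]]],
                    saliva = types_saliva$members[[ms[i]]])
    spectra <- rbind(types_tissue$X[members$tissue, , drop = FALSE],
                     types_blood$X[members$blood, , drop = FALSE],
                     types_saliva$X[members$saliva, , drop = FALSE])
    list(type_id = q,
         members = members,
         centroids = list(tissue = types_tissue$centroids[i, ],
                          blood = types_blood$centroids[mb[i], ],
                          saliva = types_saliva$centroids[ms[i], ]),
         mean_spectrum = colMeans(spectra),
         counts = vapply(members, length, integer(1)))
  })
  structure(list(types = types, tau_track = tau_track),
            class = "sers_tracking_result")
}

#' @export
print.sers_tracking_result <- function(x, ...) {
  cat(sprintf("<sers_tracking_result> %d vesicle type(s) present in all three fluids\n",
              length(x$types)))
  invisible(x)
}

#' Per-fluid source distribution of the tracked types
#'
#' @param result A `sers_tracking_result` from
#'   [match_types_across_fluids()].
#' @return Tidy `data.frame` with columns `type_id`, `tissue`, `blood`,
#'   `saliva`, `total`; empty when nothing was matched.
#' @export
source_distribution <- function(result) {
  stopifnot(inherits(result, "sers_tracking_result"))
  if (length(result$types) == 0L) {
    return(data.frame(type_id = integer(0), tissue = integer(0),
                      blood = integer(0), saliva = integer(0),
                      total = integer(0)))
  }
  rows <- lapply(result$types, function(tp) {
    data.frame(type_id = tp$type_id,
               tissue = tp$counts[["tissue"]],
               blood = tp$counts[["blood"]],
               saliva = tp$counts[["saliva"]])
  })
  out <- do.call(rbind, rows)
  out$total <- out$tissue + out$blood + out$saliva
  out
}
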