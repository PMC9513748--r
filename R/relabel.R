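#' Extract the patient-unique population (PP) and relabel
#'
#' Cancer patients also carry normal vesicles, so raw per-donor labels are
#' noisy at the single-vesicle level. This single-pass correction
#' cross-compares each patient fingerprint against the whole control set:
#' spectra whose nearest-neighbour distance to the controls is at most `tau`
#' share common spectral features with the control group and are treated as
#' common vesicles; the remainder form the patient-unique population (PP).
#' Only PP spectra keep the `"GC"` training label; common patient spectra and
#' all control spectra are labeled `"control"`.
#'
#' @param patient_X Matrix of patient fingerprints, one per row.
#' @param patient_ids Character ids for the rows of `patient_X`.
#' @param control_X Matrix of control fingerprints (>= 1 row).
#' @param tau Non-negative distance threshold, typically from
#'   [derive_threshold()] on the control set.
#' @param metric Distance metric, as in [pairwise_distances()].
#' @return A `sers_relabel`: list with `pp_ids`, `common_ids`,
#'   `threshold_used`, `nn_distance` (named per patient spectrum) and
#'   `training_labels` (patient spectrum id -> `"GC"`/`"control"`).
#' @export
extract_pp <- function(patient_X, patient_ids, control_X, tau,
                       metric = c("euclidean", "one_minus_pearson")) {
  metric <- match.arg(metric)
  patient_X <- as.matrix(patient_X)
  if (is.null(dim(control_X)) || nrow(as.matrix(control_X)) < 1L) {
    stop("control set is empty", call. = FALSE)
  }
  if (nrow(patient_X) < 1L) stop("patient set is empty", call. = FALSE)
  if (length(patient_ids) != nrow(patient_X)) {
    stop("patient_ids must match the rows of patient_X", call. = FALSE)
  }
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  patient_ids <- as.character(patient_ids)
  nn <- nearest_neighbor_distances(patient_X, control_X, metric)
  common <- nn <= tau
  labels <- ifelse(common, "control", "GC")
  names(labels) <- patient_ids
  nn_named <- as.numeric(nn)
  names(nn_named) <- patient_ids
  structure(list(pp_ids = patient_ids[!common],
                 common_ids = patient_ids[common],
                 threshold_used = tau,
                 nn_distance = nn_named,
                 training_labels = labels),
            class = "sers_relabel")
}

#' @export
print.sers_relabel <- function(x, ...) {
  cat(sprintf("<sers_relabel> %d patient spectra: %d PP, %d common (tau = %.4g)\n",
              length(x$training_labels), length(x$pp_ids),
              length(x$common_ids), x$threshold_used))
  invisible(x)
}

#' Build the relabeled training table for a cohort
#'
#' Applies a [extract_pp()] result to a cohort: PP spectra are labeled
#' `"GC"`, all other spectra (common patient spectra and every control-donor
#' spectrum) are labeled `"control"`. Rows are sorted by spectrum id so the
#' output is deterministic.
#'
#' @param cohort A [sers_cohort()] containing both groups.
#' @param result A `sers_relabel` covering every patient (`group == "GC"`)
#'   spectrum of the cohort.
#' @return List with `meta` (metadata plus a `label` column, sorted by
#'   `spectrum_id`), `X` (matching intensity rows) and `labels` (factor with
#'   levels `GC`, `control`).
#' @export
apply_relabel <- function(cohort, result) {
  stopifnot(inherits(cohort, "sers_cohort"), inherits(result, "sers_relabel"))
  patient_ids <- cohort$meta$spectrum_id[cohort$meta$group == "GC"]
  uncovered <- setdiff(patient_ids, names(result$training_labels))
  if (length(uncovered)) {
    stop("relabel result does not cover patient spectrum(s): ",
         paste(utils::head(uncovered, 5L), collapse = ", "), call. = FALSE)
  }
  ord <- order(cohort$meta$spectrum_id, method = "radix")
  meta <- cohort$meta[ord, , drop = FALSE]
  X <- cohort$X[ord, , drop = FALSE]
  label <- ifelse(meta$spectrum_id %in% result$pp_ids, "GC", "control")
  meta$label <- label
  rownames(meta) <- NULL
  list(meta = meta, X = X,
       labels = factor(label, levels = c("GC", "control")))
}

#' Paired cross-validation with and without relabeling
#'
#' Runs the repeated stratified cross-validation twice on identical splits --
#' once with the raw per-donor group labels and once with the relabeled
#' labels (PP = GC, everything else control) -- so the effect of the label
#' correction can be compared pairwise. Splits are stratified by the raw
#' group in both arms, making the train/test partitions of round r identical
#' across arms.
#'
#' @param cohort A preprocessed [sers_cohort()] for one biofluid.
#' @param percentile Percentile handed to [derive_threshold()].
#' @param rounds,train_fraction,seed See [cross_validate()].
#' @param metric Distance metric for the relabel comparison.
#' @param cost,gamma SVM settings, see [train_classifier()].
#' @return List with `relabel` and `raw` [cross_validate()] reports, the
#'   `sers_relabel` object, and `tau`.
#' @export
relabel_cv_comparison <- function(cohort, percentile = 95, rounds = 20L,
                                  train_fraction = 0.8, seed = 1L,
                                  metric = "euclidean", cost = 1,
                                  gamma = NULL) {
  stopifnot(inherits(cohort, "sers_cohort"))
  is_gc <- cohort$meta$group == "GC"
  tau <- derive_threshold(cohort$X[!is_gc, , drop = FALSE], percentile,
                          metric)
  rl <- extract_pp(cohort$X[is_gc, , drop = FALSE],
                   cohort$meta$spectrum_id[is_gc],
                   cohort$X[!is_gc, , drop = FALSE], tau, metric)
  tab <- apply_relabel(cohort, rl)
  raw_labels <- factor(tab$meta$group, levels = c("GC", "control"))
  rep_raw <- cross_validate(tab$X, raw_labels, train_fraction, rounds,
                            seed, strata = raw_labels, cost = cost,
                            gamma = gamma)
  rep_rel <- cross_validate(tab$X, tab$labels, train_fraction, rounds,
                            seed, strata = raw_labels, cost = cost,
                            gamma = gamma)
  list(relabel = rep_rel, raw = rep_raw, relabel_result = rl, tau = tau)
}
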