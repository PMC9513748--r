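#' Leave-a-pair-of-samples-out schedule
#'
#' Donor-level validation schedule: in each round, every GC donor is randomly
#' paired with a control donor, without replacement, until every donor has
#' been left out exactly once; rounds are independent repetitions. With 15
#' donors per group each round therefore has 15 pairs and 10 rounds give 150
#' held-out evaluations.
#'
#' @param gc_donors,control_donors Character vectors of donor ids; must be
#'   the same length (>= 2) with no duplicates.
#' @param rounds Number of rounds (default 10).
#' @param seed Master seed.
#' @return A `sers_lposo_schedule`: list of data frames with columns
#'   `gc_donor`, `control_donor`.
#' @export
lposo_schedule <- function(gc_donors, control_donors, rounds = 10L,
                           seed = 1L) {
  gc_donors <- as.character(gc_donors)
  control_donors <- as.character(control_donors)
  if (length(gc_donors) < 2L || length(control_donors) < 2L) {
    stop("need at least 2 donors per group", call. = FALSE)
  }
  if (length(gc_donors) != length(control_donors)) {
    stop("pairing requires equal group sizes (got ", length(gc_donors),
         " GC vs ", length(control_donors), " control donors)", call. = FALSE)
  }
  if (anyDuplicated(gc_donors) || anyDuplicated(control_donors)) {
    stop("donor ids must be unique within each group", call. = FALSE)
  }
  rounds <- as.integer(rounds)
  set.seed(as.integer(seed))
  round_seeds <- sample.int(.Machine$integer.max - 1L, rounds)
  sched <- lapply(seq_len(rounds), function(r) {
    set.seed(round_seeds[r])
    data.frame(gc_donor = sample(gc_donors),
               control_donor = sample(control_donors),
               stringsAsFactors = FALSE)
  })
  structure(sched, class = "sers_lposo_schedule", seed = as.integer(seed))
}

#' Aggregate spectrum margins to one donor-level score
#'
#' @param spectrum_margins Signed decision margins of all spectra from one
#'   donor's sample (>= 1).
#' @param aggregator `"mean"` (default: mean signed margin) or
#'   `"fraction_positive"` (share of positive calls).
#' @return A single number; larger means more GC-like.
#' @export
sample_score <- function(spectrum_margins,
                         aggregator = c("mean", "fraction_positive")) {
  aggregator <- match.arg(aggregator)
  m <- as.numeric(spectrum_margins)
  if (length(m) == 0L) stop("no spectra to aggregate", call. = FALSE)
  if (aggregator == "mean") mean(m) else mean(m > 0)
}

#' ROC curve and AUC
#'
#' The ROC is swept over all observed score thresholds (plus the endpoints).
#' The AUC is the probability that a random positive outscores a random
#' negative, with ties counted one half -- computed via the rank statistic,
#' which is exactly the trapezoidal area under the empirical ROC.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels; `positive` names the positive class.
#' @param positive Label value counted as positive (default `"GC"`).
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_and_auc <- function(scores, labels, positive = "GC") {
  scores <- as.numeric(scores)
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to sweep a ROC", call. = FALSE)
  }
  r <- rank(scores)   # midranks: ties counted one half
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  pos_sorted <- pos[ord]
  last_of_group <- c(s_sorted[-1L] != s_sorted[-length(s_sorted)], TRUE)
  tp <- cumsum(pos_sorted)[last_of_group]
  fp <- cumsum(!pos_sorted)[last_of_group]
  roc <- data.frame(threshold = c(Inf, s_sorted[last_of_group]),
                    fpr = c(0, fp / n_neg),
                    tpr = c(0, tp / n_pos))
  list(roc = roc, auc = auc)
}

#' Run the leave-a-pair-of-samples-out validation
#'
#' For every (GC donor, control donor) pair of the schedule, the model is
#' built from scratch on the remaining donors only: the relabel threshold tau
#' is derived from the training controls, the training patients are split
#' into PP/common against those controls, the SVM (bandwidth from the
#' training spectra) is trained on the relabeled labels, and the two held-out
#' donors are scored by aggregating their spectrum margins with
#' [sample_score()]. Held-out donors therefore contribute nothing to
#' training, threshold derivation, or bandwidth estimation. Per round, the
#' pooled donor scores are swept into one ROC; the mean AUC across rounds is
#' reported. A fold whose relabeled training set ends up without any PP
#' spectrum (possible when patient and control fingerprints are
#' indistinguishable) trains no model and scores its held-out donors 0
#' (neutral).
#'
#' @param cohort A preprocessed [sers_cohort()] for one biofluid with equal
#'   numbers of GC and control donors.
#' @param rounds Number of rounds (default 10).
#' @param seed Master seed for the schedule.
#' @param percentile Percentile for [derive_threshold()].
#' @param aggregator Donor-score aggregator, see [sample_score()].
#' @param relabel Apply the PP relabeling inside each training fold
#'   (default `TRUE`); `FALSE` trains on the raw group labels.
#' @param metric Distance metric for threshold/relabeling.
#' @param cost,gamma SVM settings; `gamma = NULL` re-estimates the median
#'   heuristic inside each fold.
#' @return A `sers_lposo_report`: list with `schedule`, `evaluations` (one
#'   row per held-out donor: round, donor, group, score, and the training
#'   donor set), `round_auc`, `mean_auc`, `rocs`.
#' @export
run_lposo <- function(cohort, rounds = 10L, seed = 1L, percentile = 95,
                      aggregator = c("mean", "fraction_positive"),
                      relabel = TRUE, metric = "euclidean", cost = 1,
                      gamma = NULL) {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(cohort, "sers_cohort"))
  donors <- cohort_donors(cohort)
  gc_d <- donors$donor_id[donors$group == "GC"]
  ct_d <- donors$donor_id[donors$group == "control"]
  sched <- lposo_schedule(gc_d, ct_d, rounds = rounds, seed = seed)
  evals <- list()
  rocs <- vector("list", length(sched))
  round_auc <- numeric(length(sched))
  for (r in seq_along(sched)) {
    pairs <- sched[[r]]
    scores <- numeric(0)
    labs <- character(0)
    ids <- character(0)
    for (k in seq_len(nrow(pairs))) {
      held <- c(pairs$gc_donor[k], pairs$control_donor[k])
      train_rows <- !(cohort$meta$donor_id %in% held)
      train_meta <- cohort$meta[train_rows, , drop = FALSE]
      train_X <- cohort$X[train_rows, , drop = FALSE]
      is_gc <- train_meta$group == "GC"
      if (relabel) {
        tau <- derive_threshold(train_X[!is_gc, , drop = FALSE], percentile,
                                metric)
        rl <- extract_pp(train_X[is_gc, , drop = FALSE],
                         train_meta$spectrum_id[is_gc],
                         train_X[!is_gc, , drop = FALSE], tau, metric)
        y <- ifelse(train_meta$spectrum_id %in% rl$pp_ids, "GC", "control")
      } else {
        y <- train_meta$group
      }
      # a fold whose relabeled training set has no PP spectra carries no
      # evidence of a disease-specific population: score neutrally
      model <- if (length(unique(y)) < 2L) NULL else
        train_classifier(train_X, y, cost = cost, gamma = gamma)
      for (d in held) {
        rows <- cohort$meta$donor_id == d
        margins <- if (is.null(model)) rep(0, sum(rows)) else
          decision_score(model, cohort$X[rows, , drop = FALSE])
        scores <- c(scores, sample_score(margins, aggregator))
        labs <- c(labs, donors$group[donors$donor_id == d])
        ids <- c(ids, d)
        evals[[length(evals) + 1L]] <- data.frame(
          round = r, donor_id = d,
          group = donors$group[donors$donor_id == d],
          score = scores[length(scores)],
          training_donors = paste(sort(unique(train_meta$donor_id),
                                       method = "radix"),
                                  collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    rr <- roc_and_auc(scores, labs, positive = "GC")
    rocs[[r]] <- rr$roc
    round_auc[r] <- rr$auc
  }
  structure(list(schedule = sched,
                 evaluations = do.call(rbind, evals),
                 round_auc = round_auc,
                 mean_auc = mean(round_auc),
                 rocs = rocs,
                 aggregator = aggregator,
                 relabel = relabel,
                 seed = as.integer(seed)),
            class = "sers_lposo_report")
}

#' @export
print.sers_lposo_report <- function(x, ...) {
  cat(sprintf("<sers_lposo_report> %d rounds x %d pairs: mean AUC %.3f\n",
              length(x$round_auc), nrow(x$schedule[[1L]]), x$mean_auc))
  invisible(x)
}
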