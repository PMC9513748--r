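#' Prediction accuracy
#'
#' Fraction of correct predictions: the number of matches divided by the
#' total number of predictions.
#'
#' @param predicted,truth Equal-length label vectors (>= 1).
#' @return A number in \[0, 1\].
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L || length(truth) == 0L) {
    stop("cannot score empty predictions", call. = FALSE)
  }
  if (length(predicted) != length(truth)) {
    stop("predicted and truth differ in length", call. = FALSE)
  }
  mean(as.character(predicted) == as.character(truth))
}

#' Median-heuristic RBF bandwidth
#'
#' `gamma = 1 / (2 * median(d)^2)` where `d` are the pairwise Euclidean
#' distances of the training spectra; the standard scale-free default for an
#' RBF kernel.
#'
#' @param X Training matrix, one spectrum per row.
#' @return gamma (> 0).
#' @export
median_heuristic_gamma <- function(X) {
  d <- stats::dist(as.matrix(X))
  m <- stats::median(d)
  if (!is.finite(m) || m <= 0) {
    # degenerate geometry (e.g. duplicated rows only); fall back to 1/p
    return(1 / ncol(as.matrix(X)))
  }
  1 / (2 * m^2)
}

#' Train the margin-based vesicle classifier
#'
#' Radial-basis-function support vector machine on preprocessed fingerprints.
#' Class imbalance (common after relabeling, when PP may be the minority) is
#' compensated by inverse-frequency class weights. The kernel bandwidth
#' defaults to the median pairwise-distance heuristic on the training set;
#' the regularization weight defaults to 1. Training is deterministic given
#' the data.
#'
#' @param X Training matrix, one spectrum per row.
#' @param y Binary labels; coerced to a factor whose first level is the
#'   positive class `"GC"` when present.
#' @param cost SVM regularization weight.
#' @param gamma RBF bandwidth; `NULL` (default) uses
#'   [median_heuristic_gamma()].
#' @param tolerance Termination tolerance of the SMO optimizer; the tight
#'   default makes retraining on identical data reproducible to high
#'   precision.
#' @return A `sers_svm` model supporting [predict_label()] and
#'   [decision_score()].
#' @export
train_classifier <- function(X, y, cost = 1, gamma = NULL,
                             tolerance = 1e-6) {
  X <- as.matrix(X)
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) < 2L) stop("training labels contain a single class",
                             call. = FALSE)
  if (length(lev) > 2L) stop("binary classifier requires two classes",
                             call. = FALSE)
  if (nrow(X) != length(y)) stop("X and y differ in length", call. = FALSE)
  lev <- if ("GC" %in% lev) c("GC", setdiff(lev, "GC")) else sort(lev)
  yf <- factor(y, levels = lev)
  if (is.null(gamma)) gamma <- median_heuristic_gamma(X)
  wts <- 1 / table(yf)
  wts <- wts / sum(wts) * 2
  model <- e1071::svm(X, yf, kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE, class.weights = wts,
                      tolerance = tolerance)
  structure(list(model = model, positive = lev[1L], levels = lev,
                 gamma = gamma, cost = cost),
            class = "sers_svm")
}

#' Predicted labels of a trained classifier
#' @param object A `sers_svm` from [train_classifier()].
#' @param X Matrix of spectra to classify.
#' @return Character vector of labels.
#' @export
predict_label <- function(object, X) {
  stopifnot(inherits(object, "sers_svm"))
  as.character(stats::predict(object$model, as.matrix(X)))
}

#' Signed decision margins of a trained classifier
#'
#' Positive margins vote for the positive class (`"GC"` by convention).
#'
#' @inheritParams predict_label
#' @return Numeric vector of signed margins.
#' @export
decision_score <- function(object, X) {
  stopifnot(inherits(object, "sers_svm"))
  p <- stats::predict(object$model, as.matrix(X), decision.values = TRUE)
  dv <- attr(p, "decision.values")
  scores <- dv[, 1L]
  # e1071 reports the margin of "A/B" as positive-for-A; flip if A is not
  # our positive class
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  if (!identical(first, object$positive)) scores <- -scores
  unname(scores)
}

#' Shrinkage-regularized linear discriminant projection
#'
#' Projects spectra onto at most `k - 1` discriminant directions (k classes)
#' that maximize between-class over within-class scatter. With p ~ 1023
#' features and a few hundred spectra the pooled within-class scatter is
#' singular, so it is shrunk toward a scaled identity:
#' `S_w* = (1 - shrinkage) * S_w + shrinkage * mean(diag(S_w)) * I`.
#'
#' @param X Matrix of spectra (n x p).
#' @param y Class labels (2 or 3 classes, each with >= 2 members).
#' @param n_components Number of directions; defaults to `k - 1`.
#' @param shrinkage Shrinkage intensity in \[0, 1\]; default 0.1.
#' @return A `sers_lda`: list with `directions` (p x c), `scores` (n x c;
#'   column 1 is LD1), `class_means` (on the LD scores), `center`.
#' @export
lda_project <- function(X, y, n_components = NULL, shrinkage = 0.1) {
  X <- as.matrix(X)
  y <- factor(as.character(y))
  k <- nlevels(y)
  if (k < 2L) stop("need at least 2 classes", call. = FALSE)
  if (nrow(X) <= k) stop("need more spectra than classes", call. = FALSE)
  if (shrinkage < 0 || shrinkage > 1) {
    stop("shrinkage must lie in [0, 1]", call. = FALSE)
  }
  max_c <- k - 1L
  if (is.null(n_components)) n_components <- max_c
  if (n_components > max_c) {
    stop("at most ", max_c, " discriminant component(s) exist for ", k,
         " classes", call. = FALSE)
  }
  p <- ncol(X)
  center <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (lv in levels(y)) {
    rows <- X[y == lv, , drop = FALSE]
    m <- colMeans(rows)
    cc <- sweep(rows, 2L, m)
    Sw <- Sw + crossprod(cc)
    dm <- m - center
    Sb <- Sb + nrow(rows) * tcrossprod(dm)
  }
  Sw <- Sw / (nrow(X) - k)
  Sreg <- (1 - shrinkage) * Sw
  diag(Sreg) <- diag(Sreg) + shrinkage * mean(diag(Sw))
  U <- chol(Sreg)
  # symmetric whitened between-class scatter: L^-1 Sb L^-T with L = t(U)
  B <- backsolve(U, t(backsolve(U, Sb, transpose = TRUE)), transpose = TRUE)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  W <- backsolve(U, eg$vectors[, seq_len(n_components), drop = FALSE])
  W <- sweep(W, 2L, sqrt(colSums(W^2)), `/`)
  scores <- sweep(X, 2L, center) %*% W
  colnames(scores) <- paste0("LD", seq_len(n_components))
  means <- do.call(rbind, lapply(levels(y), function(lv) {
    colMeans(scores[y == lv, , drop = FALSE])
  }))
  rownames(means) <- levels(y)
  structure(list(directions = W, scores = scores, class_means = means,
                 center = center, eigenvalues = eg$values[seq_len(n_components)],
                 shrinkage = shrinkage),
            class = "sers_lda")
}

#' Repeated stratified 80/20 cross-validation
#'
#' Each round draws, independently and without replacement, a stratified
#' random split: `train_fraction` of the spectra of each stratum train the
#' classifier, the disjoint remainder is scored with [accuracy()]. Round
#' seeds are spawned from the master seed by a counter scheme (one
#' `sample.int` stream), so the same master seed reproduces the identical
#' report.
#'
#' @param X Spectrum matrix.
#' @param y Labels used for training and scoring.
#' @param train_fraction Fraction of each stratum used for training.
#' @param rounds Number of independent rounds (default 20).
#' @param seed Master seed.
#' @param strata Stratification labels for the split; defaults to `y`.
#'   Passing the raw donor-group labels here while `y` carries relabeled
#'   labels yields splits that are identical across relabeled/raw arms.
#' @param cost,gamma Passed to [train_classifier()].
#' @return A `sers_cv_report`: list with `round_accuracies`, `mean_accuracy`,
#'   `variance`, `splits` (per-round train/test index sets) and `seed`.
#' @export
cross_validate <- function(X, y, train_fraction = 0.8, rounds = 20L,
                           seed = 1L, strata = y, cost = 1, gamma = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  strata <- as.character(strata)
  stopifnot(length(y) == nrow(X), length(strata) == nrow(X))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly inside (0, 1)", call. = FALSE)
  }
  # locale-independent stratum order so derived RNG streams are reproducible
  stratum_levels <- sort(unique(strata), method = "radix")
  if (any(table(strata) < 5L)) {
    stop("every stratum needs at least 5 spectra to split 80/20",
         call. = FALSE)
  }
  rounds <- as.integer(rounds)
  set.seed(as.integer(seed))
  round_seeds <- sample.int(.Machine$integer.max - 1L, rounds)
  acc <- numeric(rounds)
  splits <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    set.seed(round_seeds[r])
    train_idx <- integer(0)
    for (s in stratum_levels) {
      rows <- which(strata == s)
      n_train <- round(train_fraction * length(rows))
      n_train <- min(max(n_train, 1L), length(rows) - 1L)
      train_idx <- c(train_idx, sort(sample(rows, n_train)))
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_len(nrow(X)), train_idx)
    model <- train_classifier(X[train_idx, , drop = FALSE], y[train_idx],
                              cost = cost, gamma = gamma)
    pred <- predict_label(model, X[test_idx, , drop = FALSE])
    acc[r] <- accuracy(pred, y[test_idx])
    splits[[r]] <- list(train = train_idx, test = test_idx)
  }
  structure(list(round_accuracies = acc,
                 mean_accuracy = mean(acc),
                 variance = stats::var(acc),
                 splits = splits,
                 rounds = rounds,
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "sers_cv_report")
}

#' @export
print.sers_cv_report <- function(x, ...) {
  cat(sprintf("<sers_cv_report> %d rounds: mean accuracy %.3f (variance %.2g)\n",
              x$rounds, x$mean_accuracy, x$variance))
  invisible(x)
}
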