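#' Asymmetric least-squares fluorescence baseline
#'
#' Estimates the smooth fluorescence background under a Raman spectrum by
#' iteratively reweighted penalized least squares: the baseline `z` minimizes
#' `sum(w * (y - z)^2) + smoothness * sum(diff(z, differences = 2)^2)` where
#' points above the current baseline (Raman peaks) get the small weight
#' `asymmetry` and points below get `1 - asymmetry`. Iteration stops when the
#' weights no longer change or after `max_iter` sweeps.
#'
#' Defaults (`smoothness = 1e5`, `asymmetry = 0.01`) are the standard
#' operating range for broad fluorescence under narrow (~10 cm^-1) Raman
#' bands sampled at ~1 cm^-1.
#'
#' @param intensities Finite numeric vector, length >= 3.
#' @param smoothness Second-difference penalty weight (> 0).
#' @param asymmetry Weight for points above the baseline, in (0, 1).
#' @param max_iter Maximum reweighting sweeps.
#' @return The baseline vector, same length as the input.
#' @export
als_baseline <- function(intensities, smoothness = 1e5, asymmetry = 0.01,
                         max_iter = 10L) {
  y <- as.numeric(intensities)
  n <- length(y)
  if (n < 3L) stop("need at least 3 points for a baseline", call. = FALSE)
  if (!all(is.finite(y))) stop("intensities must be finite", call. = FALSE)
  if (smoothness <= 0) stop("smoothness must be positive", call. = FALSE)
  if (asymmetry <= 0 || asymmetry >= 1) {
    stop("asymmetry must lie strictly inside (0, 1)", call. = FALSE)
  }
  D <- Matrix::diff(Matrix::Diagonal(n), differences = 2L)
  P <- smoothness * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    A <- P + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y > z, asymmetry, 1 - asymmetry)
    if (identical(w_new, w)) break
    w <- w_new
  }
  z
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the centre value of the least-squares polynomial of
#' degree `polyorder` fitted over a moving window of `window` points. The
#' first and last half-windows, where no centred window exists, are filled by
#' evaluating the polynomial fitted to the first (resp. last) full window at
#' those positions, so any polynomial of degree up to `polyorder` passes
#' through the filter unchanged -- everywhere, edges included.
#'
#' @param intensities Numeric vector, length >= `window`.
#' @param window Odd window length >= 3.
#' @param polyorder Polynomial degree, < `window`.
#' @return Smoothed vector of the same length.
#' @export
sg_smooth <- function(intensities, window = 11L, polyorder = 3L) {
  y <- as.numeric(intensities)
  n <- length(y)
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (polyorder < 0L || polyorder >= window) {
    stop("polyorder must be non-negative and below the window length",
         call. = FALSE)
  }
  if (n < window) stop("series shorter than the window", call. = FALSE)
  h <- (window - 1L) %/% 2L
  cc <- sg_center_coefficients(window, polyorder)
  E <- stats::embed(y, window)   # row i = y[i+window-1], ..., y[i]
  out <- numeric(n)
  out[(h + 1L):(n - h)] <- E %*% rev(cc)
  # one-sided edges: evaluate the LS polynomial of the first/last full window
  A <- outer(seq_len(window) - 1, 0:polyorder, `^`)
  P <- A %*% solve(crossprod(A), t(A))
  out[1:h] <- (P %*% y[1:window])[1:h]
  out[(n - h + 1L):n] <- (P %*% y[(n - window + 1L):n])[(window - h + 1L):window]
  out
}

# Centre row of the SG projection: value at the window midpoint of the LS
# polynomial fit, as fixed convolution weights.
sg_center_coefficients <- function(window, polyorder) {
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  H <- A %*% solve(crossprod(A), t(A))
  H[h + 1L, ]
}

#' Min-max normalization to [0, 1]
#'
#' Proportionally compresses the intensity range of one spectrum to \[0, 1\]:
#' `(y - min) / (max - min)`. Constant spectra carry no fingerprint and are
#' refused with a condition of class `sersev_degenerate` so that cohort-level
#' preprocessing can drop and count them.
#'
#' @param intensities Numeric vector with `max > min`.
#' @return Normalized vector with min exactly 0 and max exactly 1.
#' @export
minmax_normalize <- function(intensities) {
  y <- as.numeric(intensities)
  rng <- range(y)
  if (!all(is.finite(rng))) stop("intensities must be finite", call. = FALSE)
  if (rng[1L] == rng[2L]) {
    stop(structure(class = c("sersev_degenerate", "error", "condition"),
                   list(message = "constant spectrum cannot be normalized",
                        call = NULL)))
  }
  (y - rng[1L]) / (rng[2L] - rng[1L])
}

#' Preprocessing configuration
#'
#' @param als_smoothness,als_asymmetry,als_max_iter See [als_baseline()].
#' @param sg_window,sg_polyorder See [sg_smooth()].
#' @return A list of class `sers_preprocess_config`.
#' @export
preprocess_config <- function(als_smoothness = 1e5, als_asymmetry = 0.01,
                              als_max_iter = 10L, sg_window = 11L,
                              sg_polyorder = 3L) {
  stopifnot(als_smoothness > 0, als_asymmetry > 0, als_asymmetry < 1,
            als_max_iter >= 1, sg_window >= 3, sg_window %% 2 == 1,
            sg_polyorder >= 0, sg_polyorder < sg_window)
  structure(list(als_smoothness = als_smoothness,
                 als_asymmetry = als_asymmetry,
                 als_max_iter = as.integer(als_max_iter),
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder)),
            class = "sers_preprocess_config")
}

#' Preprocess every spectrum of a cohort
#'
#' Applies, per spectrum and in this order: ALS baseline subtraction,
#' Savitzky-Golay smoothing, min-max normalization. Metadata are untouched.
#' Spectra that come out constant (degenerate, no fingerprint) are dropped;
#' their ids are recorded in the `dropped_ids` attribute and reported via a
#' message.
#'
#' @param cohort A [sers_cohort()].
#' @param config A [preprocess_config()].
#' @return The preprocessed `sers_cohort`, with attributes `dropped_ids` and
#'   `n_dropped`.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  stopifnot(inherits(cohort, "sers_cohort"),
            inherits(config, "sers_preprocess_config"))
  n <- n_spectra(cohort)
  keep <- logical(n)
  out <- matrix(NA_real_, n, cohort$grid$n)
  for (i in seq_len(n)) {
    y <- cohort$X[i, ]
    if (diff(range(y)) == 0) next   # constant input: no fingerprint
    z <- als_baseline(y, config$als_smoothness, config$als_asymmetry,
                      config$als_max_iter)
    s <- sg_smooth(y - z, config$sg_window, config$sg_polyorder)
    v <- tryCatch(minmax_normalize(s),
                  sersev_degenerate = function(e) NULL)
    if (!is.null(v)) {
      keep[i] <- TRUE
      out[i, ] <- v
    }
  }
  dropped <- cohort$meta$spectrum_id[!keep]
  if (length(dropped)) {
    message(length(dropped), " degenerate spectrum(s) dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  }
  res <- sers_cohort(cohort$meta[keep, , drop = FALSE],
                     out[keep, , drop = FALSE], cohort$grid)
  attr(res, "dropped_ids") <- dropped
  attr(res, "n_dropped") <- length(dropped)
  res
}
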