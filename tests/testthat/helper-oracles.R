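# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check (double loops, dense solves, lm fits).

# per-window polynomial least-squares smoother; one-sided at the edges
oracle_sg <- function(y, window, polyorder) {
  n <- length(y)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - h, n - window + 1L))
    xs <- (lo:(lo + window - 1L)) - i
    fit <- stats::lm.fit(outer(xs, 0:polyorder, `^`), y[lo:(lo + window - 1L)])
    out[i] <- fit$coefficients[1L]
  }
  out
}

# dense-solver ALS re-implementation (base solve, no sparse algebra)
oracle_als <- function(y, smoothness, asymmetry, max_iter) {
  n <- length(y)
  D <- diff(diag(n), differences = 2L)
  P <- smoothness * t(D) %*% D
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    z <- solve(P + diag(w), w * y)
    w_new <- ifelse(y > z, asymmetry, 1 - asymmetry)
    if (identical(w_new, w)) break
    w <- w_new
  }
  as.numeric(z)
}

# double-loop pairwise Euclidean distances
oracle_pdist <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  D
}

# exhaustive nearest-neighbour search
oracle_nn <- function(Q, R) {
  vapply(seq_len(nrow(Q)), function(i) {
    min(vapply(seq_len(nrow(R)), function(j) {
      sqrt(sum((Q[i, ] - R[j, ])^2))
    }, numeric(1)))
  }, numeric(1))
}

# all-pairs AUC with ties counted one half
oracle_auc <- function(scores, labels, positive = "GC") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# naive O(n^3) agglomerative clustering, average linkage, returning the
# sorted merge heights
oracle_average_linkage_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# piecewise-linear interpolation, one query point at a time
oracle_interp <- function(x, y, xout) {
  vapply(xout, function(q) {
    j <- max(which(x <= q))
    if (x[j] == q) return(y[j])
    y[j] + (y[j + 1L] - y[j]) * (q - x[j]) / (x[j + 1L] - x[j])
  }, numeric(1))
}
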