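#' Uniform wavenumber grid
#'
#' Defines the shared Raman-shift axis on which every spectrum in a cohort
#' lives. The axis is uniform and inclusive of both endpoints; the default
#' instance covers the biological information-rich window 553--1581 cm^-1
#' sampled at 1023 points (spacing ~1.006 cm^-1).
#'
#' @param start_wavenumber First grid point (cm^-1).
#' @param end_wavenumber Last grid point (cm^-1); must exceed `start_wavenumber`.
#' @param n_points Number of grid points (>= 2).
#' @return An object of class `sers_grid` with fields `start`, `end`, `n`.
#' @examples
#' g <- sers_grid()
#' head(wavenumbers(g))
#' @export
sers_grid <- function(start_wavenumber = 553, end_wavenumber = 1581,
                      n_points = 1023) {
  if (!is.numeric(start_wavenumber) || !is.numeric(end_wavenumber) ||
      length(start_wavenumber) != 1L || length(end_wavenumber) != 1L) {
    stop("grid endpoints must be single numbers", call. = FALSE)
  }
  if (start_wavenumber >= end_wavenumber) {
    stop("grid start must be below grid end", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) {
    stop("a grid needs at least 2 points", call. = FALSE)
  }
  structure(list(start = as.numeric(start_wavenumber),
                 end = as.numeric(end_wavenumber),
                 n = n_points),
            class = "sers_grid")
}

#' @export
print.sers_grid <- function(x, ...) {
  cat(sprintf("<sers_grid> %g to %g cm^-1, %d points (spacing %.5f cm^-1)\n",
              x$start, x$end, x$n, grid_spacing(x)))
  invisible(x)
}

#' @rdname sers_grid
#' @param grid A `sers_grid`.
#' @return `wavenumbers()`: the numeric axis of length `n_points`.
#' @export
wavenumbers <- function(grid) {
  stopifnot(inherits(grid, "sers_grid"))
  seq(grid$start, grid$end, length.out = grid$n)
}

grid_spacing <- function(grid) (grid$end - grid$start) / (grid$n - 1L)

#' Infer a uniform grid from observed wavenumber values
#'
#' Rejects axes whose successive differences deviate from the mean spacing by
#' more than `tol` times the spacing, so irregular or merged axes fail loudly
#' rather than being silently resampled.
#'
#' @param wn Sorted numeric vector of wavenumbers.
#' @param tol Relative tolerance on spacing uniformity.
#' @return A `sers_grid`.
#' @export
infer_grid <- function(wn, tol = 1e-9) {
  wn <- as.numeric(wn)
  if (length(wn) < 2L) stop("need at least 2 wavenumbers to infer a grid",
                            call. = FALSE)
  if (is.unsorted(wn, strictly = TRUE)) {
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  }
  d <- diff(wn)
  spacing <- mean(d)
  if (max(abs(d - spacing)) > tol * spacing) {
    stop("wavenumber axis is not uniform", call. = FALSE)
  }
  sers_grid(wn[1L], wn[length(wn)], length(wn))
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n == b$n &&
    abs(a$start - b$start) <= tol * grid_spacing(a) &&
    abs(a$end - b$end) <= tol * grid_spacing(a)
}
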