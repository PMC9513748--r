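#' Raman map scan container
#'
#' A map scan is a complete rectangular lattice of stage positions with one
#' spectrum per position. Fine scans localize a single vesicle (step ~0.1 um
#' under a ~1 um beam); rough scout scans (step ~2 um) find occupied spots.
#'
#' @param positions `data.frame` with numeric columns `x`, `y` (um), one row
#'   per spectrum, forming a full uniform lattice.
#' @param X Intensity matrix, `nrow(positions)` x `grid$n`.
#' @param grid A [sers_grid()].
#' @return A `sers_map_scan`: list with `xs`, `ys` (sorted unique
#'   coordinates), `step`, `values_index` (position -> row of `X`), `X`,
#'   `grid`, `positions`.
#' @export
map_scan <- function(positions, X, grid = sers_grid()) {
  stopifnot(is.data.frame(positions), all(c("x", "y") %in% names(positions)))
  X <- as.matrix(X)
  if (nrow(X) != nrow(positions)) {
    stop("positions and spectra disagree in count", call. = FALSE)
  }
  xs <- sort(unique(positions$x))
  ys <- sort(unique(positions$y))
  step_of <- function(v) {
    if (length(v) < 2L) return(NA_real_)
    d <- diff(v)
    if (max(abs(d - mean(d))) > 1e-6 * mean(d)) {
      stop("lattice coordinates are not uniform", call. = FALSE)
    }
    mean(d)
  }
  sx <- step_of(xs); sy <- step_of(ys)
  step <- if (is.na(sx)) sy else sx
  if (!is.na(sx) && !is.na(sy) && abs(sx - sy) > 1e-6 * sx) {
    stop("x and y step widths differ", call. = FALSE)
  }
  if (is.na(step) || step <= 0) stop("step width must be positive",
                                     call. = FALSE)
  if (nrow(positions) != length(xs) * length(ys)) {
    stop("positions do not form a complete rectangular lattice",
         call. = FALSE)
  }
  key <- paste(match(positions$x, xs), match(positions$y, ys))
  if (anyDuplicated(key)) stop("duplicate lattice positions", call. = FALSE)
  index <- matrix(NA_integer_, length(ys), length(xs))
  index[cbind(match(positions$y, ys), match(positions$x, xs))] <-
    seq_len(nrow(positions))
  structure(list(xs = xs, ys = ys, step = step, index = index, X = X,
                 grid = grid, positions = positions),
            class = "sers_map_scan")
}

#' Integrated band intensity of one spectrum
#'
#' Trapezoidal integral of the (optionally baseline-subtracted) intensity
#' over the window `[center - halfwidth, center + halfwidth]`. Integration is
#' used instead of peak maxima because it is robust to one-point jitter of
#' the band position.
#'
#' @param intensities Intensity vector on `grid`.
#' @param grid A [sers_grid()].
#' @param center Band centre (cm^-1), e.g. 1123 (protein), 1270
#'   (phospholipids), 1341 (nucleic acid).
#' @param halfwidth Half window width (cm^-1), default 8.
#' @param baseline `"als"` (subtract [als_baseline()] first) or `"none"`
#'   (integrate as is, for already baseline-free spectra).
#' @return The integrated band intensity (a.u. x cm^-1).
#' @export
band_intensity <- function(intensities, grid = sers_grid(), center,
                           halfwidth = 8, baseline = c("als", "none")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(grid, "sers_grid"))
  y <- as.numeric(intensities)
  if (length(y) != grid$n) stop("spectrum length does not match the grid",
                                call. = FALSE)
  lo <- center - halfwidth
  hi <- center + halfwidth
  if (lo < grid$start || hi > grid$end) {
    stop("band window [", lo, ", ", hi, "] lies outside the grid",
         call. = FALSE)
  }
  if (baseline == "als") y <- y - als_baseline(y)
  wn <- wavenumbers(grid)
  idx <- which(wn >= lo & wn <= hi)
  if (length(idx) < 2L) stop("band window covers fewer than 2 grid points",
                             call. = FALSE)
  pracma::trapz(wn[idx], y[idx])
}

#' Band-intensity heat map of a map scan
#'
#' @param scan A [map_scan()].
#' @param center,halfwidth,baseline See [band_intensity()].
#' @return A `sers_intensity_map`: list with `values` (matrix, rows = y,
#'   columns = x), `xs`, `ys`, `step`, `center`, `halfwidth`.
#' @export
build_intensity_map <- function(scan, center, halfwidth = 8,
                                baseline = c("als", "none")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(scan, "sers_map_scan"))
  band <- vapply(seq_len(nrow(scan$X)), function(i) {
    band_intensity(scan$X[i, ], scan$grid, center, halfwidth, baseline)
  }, numeric(1))
  values <- matrix(band[scan$index], nrow(scan$index), ncol(scan$index))
  structure(list(values = values, xs = scan$xs, ys = scan$ys,
                 step = scan$step, center = center, halfwidth = halfwidth),
            class = "sers_intensity_map")
}

#' Locate the hotspot of an intensity map
#'
#' The maximum of the map after 3x3 mean smoothing (zero-padded at the map
#' border, so partially-covered edge windows are not inflated). Ties go to
#' the lowest (row, column).
#'
#' @param map A `sers_intensity_map`.
#' @return Named vector `c(x =, y =)` in the map's coordinates.
#' @export
locate_hotspot <- function(map) {
  stopifnot(inherits(map, "sers_intensity_map"))
  v <- map$values
  if (max(v) == min(v)) {
    stop("constant map has no hotspot", call. = FALSE)
  }
  nr <- nrow(v); nc <- ncol(v)
  sm <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1L, i - 1L):min(nr, i + 1L)
    for (j in seq_len(nc)) {
      cj <- max(1L, j - 1L):min(nc, j + 1L)
      sm[i, j] <- sum(v[ri, cj]) / 9
    }
  }
  best <- which(sm == max(sm), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  c(x = map$xs[best[["col"]]], y = map$ys[best[["row"]]])
}

#' Pairwise co-localization of band maps
#'
#' Pearson correlation of the flattened intensity maps for every pair; high
#' correlations across marker bands (protein / phospholipid / nucleic acid)
#' indicate the substances co-exist in the same diffraction-limited spot.
#'
#' @param maps List of >= 2 `sers_intensity_map` objects of equal shape.
#' @return `data.frame` with columns `map_a`, `map_b`, `correlation`.
#' @export
colocalization <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 2L)
  shapes <- vapply(maps, function(m) paste(dim(m$values), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) {
    stop("maps differ in shape", call. = FALSE)
  }
  if (any(vapply(maps, function(m) stats::sd(m$values) == 0, logical(1)))) {
    stop("constant map: correlation undefined", call. = FALSE)
  }
  nm <- names(maps)
  if (is.null(nm)) nm <- as.character(seq_along(maps))
  pairs <- utils::combn(seq_along(maps), 2L)
  data.frame(
    map_a = nm[pairs[1L, ]],
    map_b = nm[pairs[2L, ]],
    correlation = apply(pairs, 2L, function(p) {
      stats::cor(as.vector(maps[[p[1L]]]$values),
                 as.vector(maps[[p[2L]]]$values))
    }))
}
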