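#' Read a spectral table into a cohort
#'
#' Two plain-CSV dialects are supported. `long` has one row per
#' (spectrum, wavenumber) with columns `spectrum_id, donor_id, group, fluid,
#' wavenumber, intensity`; `wide` has one row per spectrum with the four
#' metadata columns followed by one column per grid point (column names are
#' the wavenumber values). The grid is inferred from the wavenumbers and must
#' be uniform and identical across spectra.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @return A [sers_cohort()].
#' @seealso [write_spectrum_table()]
#' @export
read_spectrum_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = NULL, data.table = TRUE,
                          showProgress = FALSE)
  meta_cols <- c("spectrum_id", "donor_id", "group", "fluid")
  if (dialect == "long") {
    need <- c(meta_cols, "wavenumber", "intensity")
    missing_cols <- setdiff(need, names(dt))
    if (length(missing_cols)) {
      stop("long table is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    if (nrow(dt) == 0L) {
      stop("long table has no rows; the grid cannot be inferred",
           call. = FALSE)
    }
    if (anyDuplicated(dt[, c("spectrum_id", "wavenumber")])) {
      stop("duplicate (spectrum_id, wavenumber) rows", call. = FALSE)
    }
    ids <- unique(dt$spectrum_id)   # keep first-appearance order
    data.table::set(dt, j = ".spec_order", value = match(dt$spectrum_id, ids))
    data.table::setorderv(dt, c(".spec_order", "wavenumber"))
    wn_ref <- dt$wavenumber[dt$spectrum_id == ids[1L]]
    grid <- infer_grid(wn_ref)
    counts <- table(dt$spectrum_id)
    if (any(counts != grid$n)) {
      stop("spectra disagree on the wavenumber grid", call. = FALSE)
    }
    wn_all <- matrix(dt$wavenumber, nrow = grid$n)
    if (max(abs(wn_all - wn_ref)) > 1e-9 * grid_spacing(grid)) {
      stop("spectra disagree on the wavenumber grid", call. = FALSE)
    }
    X <- matrix(dt$intensity, nrow = length(ids), ncol = grid$n, byrow = TRUE)
    meta <- unique(as.data.frame(dt)[meta_cols])
    meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
    sers_cohort(meta, X, grid)
  } else {
    missing_cols <- setdiff(meta_cols, names(dt))
    if (length(missing_cols)) {
      stop("wide table is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    wn_names <- setdiff(names(dt), meta_cols)
    wn <- suppressWarnings(as.numeric(wn_names))
    if (length(wn) == 0L || anyNA(wn)) {
      stop("wide table header must carry numeric wavenumber columns",
           call. = FALSE)
    }
    grid <- infer_grid(wn)
    meta <- as.data.frame(dt)[meta_cols]
    X <- as.matrix(as.data.frame(dt)[wn_names])
    storage.mode(X) <- "double"
    sers_cohort(meta, X, grid)
  }
}

#' Write a cohort as a spectral table
#'
#' Writes the CSV dialects read by [read_spectrum_table()] (round trip is
#' lossless: metadata bit-exact, intensities to full double precision), plus
#' an optional JSON manifest `<path>.manifest.json` recording the grid,
#' spectrum/donor counts and any provenance the caller supplies.
#'
#' @param cohort A [sers_cohort()].
#' @param path Output CSV path.
#' @param dialect `"long"` or `"wide"`.
#' @param manifest Write the JSON manifest alongside? Default `TRUE`.
#' @param provenance Optional named list (e.g. seed, config hash) stored
#'   verbatim in the manifest.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(cohort, path, dialect = c("long", "wide"),
                                 manifest = TRUE, provenance = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(cohort, "sers_cohort"))
  wn <- wavenumbers(cohort$grid)
  n <- n_spectra(cohort)
  if (dialect == "long") {
    if (n == 0L) {
      dt <- data.table::data.table(spectrum_id = character(0),
                                   donor_id = character(0),
                                   group = character(0), fluid = character(0),
                                   wavenumber = numeric(0),
                                   intensity = numeric(0))
    } else {
      idx <- rep(seq_len(n), each = cohort$grid$n)
      dt <- data.table::data.table(
        spectrum_id = cohort$meta$spectrum_id[idx],
        donor_id = cohort$meta$donor_id[idx],
        group = cohort$meta$group[idx],
        fluid = cohort$meta$fluid[idx],
        wavenumber = rep(wn, times = n),
        intensity = as.vector(t(cohort$X)))
    }
  } else {
    dt <- data.table::as.data.table(cohort$meta)
    if (n == 0L) {
      for (w in format_wavenumber(wn)) dt[[w]] <- numeric(0)
    } else {
      Xdt <- data.table::as.data.table(cohort$X)
      data.table::setnames(Xdt, format_wavenumber(wn))
      dt <- cbind(dt, Xdt)
    }
  }
  data.table::fwrite(dt, path, sep = ",", quote = FALSE,
                     showProgress = FALSE)
  if (manifest) {
    man <- list(grid = list(start_wavenumber = cohort$grid$start,
                            end_wavenumber = cohort$grid$end,
                            n_points = cohort$grid$n),
                dialect = dialect,
                n_spectra = n,
                n_donors = length(unique(cohort$meta$donor_id)),
                groups = as.list(table(cohort$meta$group)),
                fluids = as.list(table(cohort$meta$fluid)))
    if (!is.null(provenance)) man$provenance <- provenance
    jsonlite::write_json(man, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

format_wavenumber <- function(wn) sprintf("%.17g", wn)

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation from a native (possibly non-uniform) axis onto a
#' uniform target grid; values at shared knots are preserved exactly. No
#' smoothing is performed here -- denoising belongs to the preprocessing
#' stage. Extrapolation is refused.
#'
#' @param native_axis Strictly increasing wavenumber axis of the measurement.
#' @param intensities Intensities on `native_axis`.
#' @param grid Target [sers_grid()].
#' @return Numeric vector of length `grid$n`.
#' @export
resample_to_grid <- function(native_axis, intensities, grid = sers_grid()) {
  stopifnot(inherits(grid, "sers_grid"))
  native_axis <- as.numeric(native_axis)
  intensities <- as.numeric(intensities)
  if (length(native_axis) != length(intensities)) {
    stop("axis and intensities differ in length", call. = FALSE)
  }
  if (is.unsorted(native_axis, strictly = TRUE)) {
    stop("native axis must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (native_axis[1L] > grid$start ||
      native_axis[length(native_axis)] < grid$end) {
    stop("target grid lies outside the native axis span; refusing to ",
         "extrapolate", call. = FALSE)
  }
  stats::approx(native_axis, intensities, xout = wavenumbers(grid),
                method = "linear", ties = "ordered")$y
}
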