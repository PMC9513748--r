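#' Cohort of single-vesicle spectra
#'
#' A cohort bundles one intensity matrix (one row per measured vesicle) with
#' per-spectrum metadata and the shared wavenumber grid. This is the unit all
#' downstream modules (preprocessing, relabeling, classification, validation,
#' tracking) operate on.
#'
#' Invariants enforced at construction: all spectra share the grid length,
#' spectrum ids are unique, every donor belongs to exactly one group, and all
#' intensities are finite.
#'
#' @param meta `data.frame` with columns `spectrum_id`, `donor_id`, `group`
#'   (one of `"GC"`, `"control"`), `fluid` (one of `"tissue"`, `"blood"`,
#'   `"saliva"`).
#' @param intensities Numeric matrix, `nrow(meta)` rows by `grid$n` columns.
#' @param grid A [sers_grid()].
#' @return An object of class `sers_cohort` with fields `meta`, `X`, `grid`.
#' @export
sers_cohort <- function(meta, intensities, grid = sers_grid()) {
  stopifnot(inherits(grid, "sers_grid"))
  required <- c("spectrum_id", "donor_id", "group", "fluid")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta <- as.data.frame(meta)[required]
  meta$spectrum_id <- as.character(meta$spectrum_id)
  meta$donor_id <- as.character(meta$donor_id)
  meta$group <- as.character(meta$group)
  meta$fluid <- as.character(meta$fluid)
  intensities <- as.matrix(intensities)
  if (nrow(meta) == 0L) {
    intensities <- matrix(numeric(0), nrow = 0L, ncol = grid$n)
  }
  if (nrow(intensities) != nrow(meta)) {
    stop("metadata and intensity matrix disagree on the number of spectra",
         call. = FALSE)
  }
  if (nrow(intensities) > 0L && ncol(intensities) != grid$n) {
    stop("intensity matrix has ", ncol(intensities),
         " columns but the grid has ", grid$n, " points", call. = FALSE)
  }
  if (anyDuplicated(meta$spectrum_id)) {
    stop("spectrum ids must be unique", call. = FALSE)
  }
  bad_group <- setdiff(unique(meta$group), c("GC", "control"))
  if (length(bad_group)) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  bad_fluid <- setdiff(unique(meta$fluid), c("tissue", "blood", "saliva"))
  if (length(bad_fluid)) {
    stop("unknown fluid label(s): ", paste(bad_fluid, collapse = ", "),
         call. = FALSE)
  }
  dg <- unique(meta[c("donor_id", "group")])
  if (anyDuplicated(dg$donor_id)) {
    stop("each donor must map to exactly one group", call. = FALSE)
  }
  if (length(intensities) && !all(is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  rownames(intensities) <- meta$spectrum_id
  rownames(meta) <- NULL
  structure(list(meta = meta, X = intensities, grid = grid),
            class = "sers_cohort")
}

#' @export
print.sers_cohort <- function(x, ...) {
  cat(sprintf("<sers_cohort> %d spectra, %d donors (%s), grid %g-%g cm^-1 x %d\n",
              nrow(x$meta), length(unique(x$meta$donor_id)),
              paste(sprintf("%s: %d", names(table(x$meta$group)),
                            as.integer(table(x$meta$group))), collapse = ", "),
              x$grid$start, x$grid$end, x$grid$n))
  invisible(x)
}

#' Number of spectra in a cohort
#' @param cohort A `sers_cohort`.
#' @return Integer count.
#' @export
n_spectra <- function(cohort) nrow(cohort$meta)

#' Subset a cohort by a logical or index vector over spectra
#'
#' @param cohort A `sers_cohort`.
#' @param i Logical vector of length `n_spectra(cohort)` or integer indices.
#' @return The reduced `sers_cohort`.
#' @export
subset_cohort <- function(cohort, i) {
  sers_cohort(cohort$meta[i, , drop = FALSE],
              cohort$X[i, , drop = FALSE],
              cohort$grid)
}

#' Donor table of a cohort
#'
#' @param cohort A `sers_cohort`.
#' @return `data.frame` with one row per donor: `donor_id`, `group`,
#'   `n_spectra`.
#' @export
cohort_donors <- function(cohort) {
  if (nrow(cohort$meta) == 0L) {
    return(data.frame(donor_id = character(0), group = character(0),
                      n_spectra = integer(0)))
  }
  tab <- table(cohort$meta$donor_id)
  dg <- unique(cohort$meta[c("donor_id", "group")])
  dg <- dg[order(dg$donor_id, method = "radix"), , drop = FALSE]
  dg$n_spectra <- as.integer(tab[dg$donor_id])
  rownames(dg) <- NULL
  dg
}
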