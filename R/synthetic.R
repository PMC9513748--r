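#' Default Raman peak library for synthetic vesicle subtypes
#'
#' Candidate band centres spanning the 553--1581 cm^-1 window, including the
#' protein (1123), phospholipid (1270) and nucleic-acid (1341 cm^-1) marker
#' bands used for map heat-mapping.
#'
#' @return `data.frame` with columns `center`, `height`, `width` (Lorentzian
#'   half-width at half-maximum, cm^-1).
#' @export
default_peak_library <- function() {
  centers <- c(563, 598, 640, 678, 715, 752, 790, 828, 865, 900, 935, 968,
               1002, 1040, 1075, 1123, 1160, 1200, 1235, 1270, 1305, 1341,
               1380, 1420, 1460, 1500, 1540, 1570)
  data.frame(center = centers,
             height = rep(1, length(centers)),
             width = rep(8, length(centers)))
}

#' Draw a random vesicle subtype template
#'
#' A subtype is a random subset of library bands with random heights and
#' Lorentzian widths; different subtypes differ in which bands they carry and
#' how strongly, emulating vesicle sub-populations with distinct biochemical
#' composition.
#'
#' @param peak_library `data.frame` of candidate bands, see
#'   [default_peak_library()].
#' @param n_peaks Length-2 range (min, max) of bands per subtype.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A `sers_template`: list with `peaks` (`center`, `height`, `width`),
#'   `type_id`, `uniqueness`, `cross_fluid`.
#' @export
make_subtype_template <- function(peak_library = default_peak_library(),
                                  n_peaks = c(4L, 8L), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (nrow(peak_library) == 0L) stop("peak library is empty", call. = FALSE)
  n_peaks <- as.integer(n_peaks)
  if (length(n_peaks) == 1L) n_peaks <- c(n_peaks, n_peaks)
  if (max(n_peaks) > nrow(peak_library)) {
    stop("asked for more peaks than the library holds", call. = FALSE)
  }
  k <- if (n_peaks[1L] == n_peaks[2L]) n_peaks[1L] else
    sample(seq(n_peaks[1L], n_peaks[2L]), 1L)
  idx <- sort(sample.int(nrow(peak_library), k))
  peaks <- data.frame(center = peak_library$center[idx],
                      height = stats::runif(k, 0.3, 1.0),
                      width = stats::runif(k, 5, 12))
  structure(list(peaks = peaks, type_id = NA_character_,
                 uniqueness = NA_character_, cross_fluid = FALSE),
            class = "sers_template")
}

#' Render a template as a clean spectrum
#'
#' Sum of Lorentzian lines `h / (1 + ((x - c) / w)^2)` evaluated on the grid.
#'
#' @param template A `sers_template`.
#' @param grid A [sers_grid()].
#' @return Numeric vector of length `grid$n`.
#' @export
render_template <- function(template, grid = sers_grid()) {
  stopifnot(inherits(template, "sers_template"))
  wn <- wavenumbers(grid)
  y <- numeric(grid$n)
  for (i in seq_len(nrow(template$peaks))) {
    p <- template$peaks[i, ]
    y <- y + p$height / (1 + ((wn - p$center) / p$width)^2)
  }
  y
}

#' Simulate one measured vesicle spectrum
#'
#' One noisy realization of a subtype template: per-peak height jitter and a
#' global multiplicative amplitude factor (both lognormal), uniform peak
#' position jitter, a smooth fluorescence-like background (random quadratic
#' plus one broad Gaussian), and additive white noise. With all four settings
#' at zero the clean template rendering is returned.
#'
#' @param template A `sers_template`.
#' @param grid A [sers_grid()].
#' @param amplitude_sigma Lognormal sigma of the global amplitude factor
#'   (per-peak jitter uses `amplitude_sigma / 2`).
#' @param shift_max Peak-centre jitter, uniform on +/- `shift_max` cm^-1.
#' @param baseline_amplitude Scale of the fluorescence background relative to
#'   unit peak height.
#' @param noise_sd Additive white-noise standard deviation.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of length `grid$n`.
#' @export
sample_vesicle_spectrum <- function(template, grid = sers_grid(),
                                    amplitude_sigma = 0.15, shift_max = 1.0,
                                    baseline_amplitude = 0.5,
                                    noise_sd = 0.01, seed = NULL) {
  stopifnot(inherits(template, "sers_template"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  wn <- wavenumbers(grid)
  k <- nrow(template$peaks)
  amp <- exp(stats::rnorm(1L, 0, amplitude_sigma))
  h <- template$peaks$height * exp(stats::rnorm(k, 0, amplitude_sigma / 2))
  cen <- template$peaks$center + stats::runif(k, -shift_max, shift_max)
  y <- numeric(grid$n)
  for (i in seq_len(k)) {
    y <- y + h[i] / (1 + ((wn - cen[i]) / template$peaks$width[i])^2)
  }
  y <- amp * y
  t01 <- (wn - grid$start) / (grid$end - grid$start)
  cf <- stats::runif(3L, 0, 1)
  g_h <- stats::runif(1L, 0.5, 1.5)
  g_mu <- stats::runif(1L, grid$start, grid$end)
  g_s <- stats::runif(1L, 150, 400)
  bl <- baseline_amplitude *
    (cf[1L] + cf[2L] * t01 + cf[3L] * t01^2 +
       g_h * exp(-(wn - g_mu)^2 / (2 * g_s^2)))
  y + bl + stats::rnorm(grid$n, 0, noise_sd)
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the clinical study design this generator emulates: 15
#' donors per group, roughly 50--70 single-vesicle spectra per sample, and a
#' patient-unique vesicle fraction that drops from tissue (0.7) through blood
#' (0.4) to saliva (0.15), because disease-specific vesicles are diluted by
#' normal vesicles once they circulate in the bodily fluids. Nine
#' patient-unique subtypes are flagged cross-fluid so they can be tracked
#' across tissue, blood and saliva.
#'
#' @param donors_per_group Donors per group (GC and control).
#' @param spectra_per_sample Length-2 inclusive range of spectra per
#'   donor-fluid sample.
#' @param n_shared_subtypes Vesicle subtypes common to both groups.
#' @param n_unique_subtypes Group-unique distractor subtypes per group *per
#'   fluid* (on top of the cross-fluid types for GC).
#' @param n_cross_fluid_types GC-unique subtypes present in all three fluids.
#' @param unique_fraction Named fractions of group-unique spectra per fluid.
#' @param subtype_prevalence Probability that a given donor carries a given
#'   subtype of their *group-unique* pool (donor heterogeneity; no unique
#'   subtype is guaranteed pan-patient). Shared subtypes are carried by
#'   every donor.
#' @param amplitude_sigma,shift_max,baseline_amplitude,noise_sd Spectrum
#'   noise model, see [sample_vesicle_spectrum()].
#' @param n_peaks Bands per subtype, see [make_subtype_template()].
#' @param fluids Fluids to generate.
#' @param grid Wavenumber grid.
#' @param seed Master seed; the full output (cohorts and ground truth) is a
#'   deterministic function of the config including this seed.
#' @return A `sers_sim_config` list.
#' @export
sim_config <- function(donors_per_group = 15L,
                       spectra_per_sample = c(50L, 70L),
                       n_shared_subtypes = 8L,
                       n_unique_subtypes = 6L,
                       n_cross_fluid_types = 9L,
                       unique_fraction = c(tissue = 0.7, blood = 0.4,
                                           saliva = 0.15),
                       subtype_prevalence = 0.7,
                       amplitude_sigma = 0.15,
                       shift_max = 1.0,
                       baseline_amplitude = 0.5,
                       noise_sd = 0.01,
                       n_peaks = c(4L, 8L),
                       fluids = c("tissue", "blood", "saliva"),
                       grid = sers_grid(),
                       seed = 42L) {
  fluids <- match.arg(fluids, c("tissue", "blood", "saliva"),
                      several.ok = TRUE)
  if (any(unique_fraction < 0) || any(unique_fraction > 1)) {
    stop("unique fractions must lie in [0, 1]", call. = FALSE)
  }
  missing_f <- setdiff(fluids, names(unique_fraction))
  if (length(missing_f)) {
    stop("unique_fraction missing for fluid(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  if (donors_per_group < 1L || n_shared_subtypes < 1L ||
      n_cross_fluid_types < 0L || n_unique_subtypes < 0L) {
    stop("counts must be positive (subtype/donor) or non-negative (unique)",
         call. = FALSE)
  }
  if (length(spectra_per_sample) != 2L ||
      spectra_per_sample[1L] > spectra_per_sample[2L] ||
      spectra_per_sample[1L] < 1L) {
    stop("spectra_per_sample must be an increasing positive range",
         call. = FALSE)
  }
  if (subtype_prevalence <= 0 || subtype_prevalence > 1) {
    stop("subtype_prevalence must lie in (0, 1]", call. = FALSE)
  }
  structure(list(donors_per_group = as.integer(donors_per_group),
                 spectra_per_sample = as.integer(spectra_per_sample),
                 n_shared_subtypes = as.integer(n_shared_subtypes),
                 n_unique_subtypes = as.integer(n_unique_subtypes),
                 n_cross_fluid_types = as.integer(n_cross_fluid_types),
                 unique_fraction = unique_fraction,
                 subtype_prevalence = subtype_prevalence,
                 amplitude_sigma = amplitude_sigma,
                 shift_max = shift_max,
                 baseline_amplitude = baseline_amplitude,
                 noise_sd = noise_sd,
                 n_peaks = as.integer(n_peaks),
                 fluids = fluids,
                 grid = grid,
                 seed = as.integer(seed)),
            class = "sers_sim_config")
}

#' Generate a synthetic single-vesicle SERS cohort with ground truth
#'
#' Builds the subtype templates (shared, GC-unique incl. cross-fluid,
#' control-unique), gives every donor the full shared pool plus a random
#' personal subset of their group-unique pool, then draws every spectrum:
#' for a GC donor in fluid f a spectrum is GC-unique with probability
#' `unique_fraction[f]` and shared otherwise; control donors mirror this
#' with control-unique subtypes. The returned
#' ground truth records, for every spectrum, its subtype and whether it is
#' shared or group-unique -- the labels all recovery tests compare against.
#'
#' @param config A [sim_config()].
#' @return List with `cohorts` (named list of raw [sers_cohort()] per fluid),
#'   `truth` (`data.frame`: `spectrum_id`, `donor_id`, `group`, `fluid`,
#'   `type_id`, `uniqueness`, `cross_fluid`), `templates`, `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sers_sim_config"))
  set.seed(config$seed)
  lib <- default_peak_library()
  new_template <- function(type_id, uniqueness, cross_fluid = FALSE) {
    tp <- make_subtype_template(lib, config$n_peaks)
    tp$type_id <- type_id
    tp$uniqueness <- uniqueness
    tp$cross_fluid <- cross_fluid
    tp
  }
  templates <- list()
  for (i in seq_len(config$n_shared_subtypes)) {
    templates[[paste0("SH", i)]] <- new_template(paste0("SH", i), "shared")
  }
  for (i in seq_len(config$n_cross_fluid_types)) {
    templates[[paste0("XF", i)]] <-
      new_template(paste0("XF", i), "GC-unique", cross_fluid = TRUE)
  }
  per_fluid_unique <- list()
  for (f in config$fluids) {
    per_fluid_unique[[f]] <- list(gc = character(0), control = character(0))
    for (i in seq_len(config$n_unique_subtypes)) {
      id <- paste0("GU_", f, "_", i)
      templates[[id]] <- new_template(id, "GC-unique")
      per_fluid_unique[[f]]$gc <- c(per_fluid_unique[[f]]$gc, id)
      id <- paste0("CU_", f, "_", i)
      templates[[id]] <- new_template(id, "control-unique")
      per_fluid_unique[[f]]$control <- c(per_fluid_unique[[f]]$control, id)
    }
  }
  shared_ids <- paste0("SH", seq_len(config$n_shared_subtypes))
  xf_ids <- if (config$n_cross_fluid_types > 0L) {
    paste0("XF", seq_len(config$n_cross_fluid_types))
  } else character(0)

  donors <- data.frame(
    donor_id = c(sprintf("GC%02d", seq_len(config$donors_per_group)),
                 sprintf("C%02d", seq_len(config$donors_per_group))),
    group = rep(c("GC", "control"), each = config$donors_per_group),
    stringsAsFactors = FALSE)

  draw_subset <- function(pool) {
    if (length(pool) == 0L) return(character(0))
    keep <- stats::runif(length(pool)) < config$subtype_prevalence
    if (!any(keep)) keep[sample.int(length(pool), 1L)] <- TRUE
    pool[keep]
  }
  # every donor carries the full shared pool (normal vesicle types are, by
  # definition, common to everyone); heterogeneity applies to the
  # group-unique pools, so no unique subtype is guaranteed pan-patient
  donor_pools <- lapply(seq_len(nrow(donors)), function(i) {
    pool <- list(shared = shared_ids)
    if (donors$group[i] == "GC") {
      pool$cross_fluid <- draw_subset(xf_ids)
      for (f in config$fluids) {
        pool[[paste0("unique_", f)]] <-
          draw_subset(per_fluid_unique[[f]]$gc)
      }
    } else {
      for (f in config$fluids) {
        pool[[paste0("unique_", f)]] <-
          draw_subset(per_fluid_unique[[f]]$control)
      }
    }
    pool
  })
  names(donor_pools) <- donors$donor_id

  cohorts <- list()
  truth <- list()
  for (f in config$fluids) {
    meta <- list()
    rows <- list()
    for (i in seq_len(nrow(donors))) {
      d <- donors$donor_id[i]
      g <- donors$group[i]
      pool <- donor_pools[[d]]
      uniq_pool <- pool[[paste0("unique_", f)]]
      if (g == "GC") uniq_pool <- c(pool$cross_fluid, uniq_pool)
      n_spec <- sample(seq(config$spectra_per_sample[1L],
                           config$spectra_per_sample[2L]), 1L)
      for (s in seq_len(n_spec)) {
        take_unique <- length(uniq_pool) > 0L &&
          stats::runif(1L) < config$unique_fraction[[f]]
        type <- if (take_unique) {
          uniq_pool[sample.int(length(uniq_pool), 1L)]
        } else {
          pool$shared[sample.int(length(pool$shared), 1L)]
        }
        tp <- templates[[type]]
        y <- sample_vesicle_spectrum(tp, config$grid,
                                     config$amplitude_sigma,
                                     config$shift_max,
                                     config$baseline_amplitude,
                                     config$noise_sd)
        sid <- sprintf("%s_%s_%03d", d, f, s)
        meta[[length(meta) + 1L]] <- data.frame(
          spectrum_id = sid, donor_id = d, group = g, fluid = f,
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- y
        truth[[length(truth) + 1L]] <- data.frame(
          spectrum_id = sid, donor_id = d, group = g, fluid = f,
          type_id = tp$type_id, uniqueness = tp$uniqueness,
          cross_fluid = tp$cross_fluid, stringsAsFactors = FALSE)
      }
    }
    cohorts[[f]] <- sers_cohort(do.call(rbind, meta),
                                do.call(rbind, rows), config$grid)
  }
  list(cohorts = cohorts, truth = do.call(rbind, truth),
       templates = templates, config = config)
}

#' Generate a synthetic Raman map scan
#'
#' Forward model of a fine map over point emitters under a Gaussian beam:
#' the spectrum at lattice position `(x, y)` is the template scaled by the
#' summed beam weights `amplitude * exp(-d^2 / (2 sigma^2))` over all
#' emitters, plus white noise. The default beam sigma (0.42 um) makes the
#' convolved spot ~1 um across, matching a tightly focused visible beam.
#'
#' @param emitters `data.frame` with columns `x`, `y` (um) and optionally
#'   `amplitude` (default 1); all emitters must lie inside `extent`.
#' @param template A `sers_template` rendered at each position.
#' @param beam_sigma Gaussian beam sigma (um).
#' @param step Lattice step width (um), default 0.1 (fine mapping).
#' @param extent `c(xmin, xmax, ymin, ymax)` in um.
#' @param noise_sd Additive white-noise sd per spectral point.
#' @param grid Wavenumber grid.
#' @param seed Optional seed for the noise.
#' @return A [map_scan()].
#' @export
generate_map_scan <- function(emitters, template, beam_sigma = 0.42,
                              step = 0.1, extent = c(0, 2, 0, 2),
                              noise_sd = 0, grid = sers_grid(),
                              seed = NULL) {
  stopifnot(is.data.frame(emitters), all(c("x", "y") %in% names(emitters)))
  if (is.null(emitters$amplitude)) emitters$amplitude <- 1
  if (any(emitters$x < extent[1L] | emitters$x > extent[2L] |
          emitters$y < extent[3L] | emitters$y > extent[4L])) {
    stop("all emitters must lie inside the extent", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  xs <- seq(extent[1L], extent[2L], by = step)
  ys <- seq(extent[3L], extent[4L], by = step)
  pos <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  base <- render_template(template, grid)
  w <- numeric(nrow(pos))
  for (e in seq_len(nrow(emitters))) {
    d2 <- (pos$x - emitters$x[e])^2 + (pos$y - emitters$y[e])^2
    w <- w + emitters$amplitude[e] * exp(-d2 / (2 * beam_sigma^2))
  }
  X <- tcrossprod(w, base)
  if (noise_sd > 0) {
    X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X), ncol(X))
  }
  map_scan(pos, X, grid)
}
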