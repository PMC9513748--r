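test_that("subtype templates are deterministic and pairwise distinct", {
  t1 <- make_subtype_template(seed = 80)
  t2 <- make_subtype_template(seed = 80)
  expect_identical(t1, t2)

  lib <- default_peak_library()
  all_peaks <- make_subtype_template(lib, n_peaks = nrow(lib), seed = 81)
  expect_equal(nrow(all_peaks$peaks), nrow(lib))
  expect_error(make_subtype_template(lib, n_peaks = nrow(lib) + 1),
               "more peaks")

  g <- small_grid(128L)
  set.seed(82)
  rendered <- t(vapply(seq_len(40), function(i) {
    render_template(make_subtype_template(), g)
  }, numeric(g$n)))
  D <- pairwise_distances(rendered)$values
  expect_gt(min(D[upper.tri(D)]), 0)
})

test_that("vesicle spectra: noise-free limit and within/between margins", {
  # margins are assessed on the native grid: the baseline-removal defaults
  # are tuned for ~1 cm^-1 spacing
  g <- sers_grid()
  tpl <- make_subtype_template(seed = 83)
  clean <- sample_vesicle_spectrum(tpl, g, amplitude_sigma = 0, shift_max = 0,
                                   baseline_amplitude = 0, noise_sd = 0,
                                   seed = 1)
  expect_equal(clean, render_template(tpl, g))

  tpl2 <- make_subtype_template(seed = 84)
  prep <- function(tpl, k) t(vapply(seq_len(k), function(i) {
    y <- sample_vesicle_spectrum(tpl, g)
    minmax_normalize(sg_smooth(y - als_baseline(y)))
  }, numeric(g$n)))
  set.seed(85)
  A <- prep(tpl, 6); B <- prep(tpl2, 6)
  d_within <- pairwise_distances(A)$values
  d_between <- cross_distances(A, B)
  expect_lt(max(d_within), min(d_between))

  flat <- list(peaks = data.frame(center = numeric(0), height = numeric(0),
                                  width = numeric(0)),
               type_id = "none", uniqueness = "shared", cross_fluid = FALSE)
  class(flat) <- "sers_template"
  y <- sample_vesicle_spectrum(flat, g, noise_sd = 0, baseline_amplitude = 0,
                               seed = 2)
  expect_error(minmax_normalize(y), class = "sersev_degenerate")
})

test_that("generated cohorts honour the configured structure exactly", {
  cfg <- sim_config(donors_per_group = 5L, spectra_per_sample = c(8L, 12L),
                    grid = sers_grid(553, 1581, 128L), seed = 42L)
  sim <- generate_cohort(cfg)
  expect_setequal(names(sim$cohorts), c("tissue", "blood", "saliva"))
  for (f in names(sim$cohorts)) {
    co <- sim$cohorts[[f]]
    donors <- cohort_donors(co)
    expect_equal(sum(donors$group == "GC"), 5L)
    expect_equal(sum(donors$group == "control"), 5L)
    expect_true(all(donors$n_spectra >= 8L & donors$n_spectra <= 12L))
  }
  # ground truth covers every generated spectrum exactly once
  all_ids <- unlist(lapply(sim$cohorts, function(co) co$meta$spectrum_id))
  expect_setequal(sim$truth$spectrum_id, all_ids)
  expect_equal(anyDuplicated(sim$truth$spectrum_id), 0L)
  # control donors never carry GC-unique types and vice versa
  expect_false(any(sim$truth$group == "control" &
                     sim$truth$uniqueness == "GC-unique"))
  expect_false(any(sim$truth$group == "GC" &
                     sim$truth$uniqueness == "control-unique"))

  # full determinism under the master seed
  sim2 <- generate_cohort(cfg)
  expect_identical(sim$truth, sim2$truth)
  for (f in names(sim$cohorts)) {
    expect_identical(sim$cohorts[[f]]$X, sim2$cohorts[[f]]$X)
  }
})

test_that("realized unique fractions track the configured fractions", {
  cfg <- sim_config(donors_per_group = 8L, spectra_per_sample = c(25L, 35L),
                    grid = sers_grid(553, 1581, 64L), seed = 43L)
  sim <- generate_cohort(cfg)
  for (f in names(cfg$unique_fraction)) {
    tr <- sim$truth[sim$truth$fluid == f & sim$truth$group == "GC", ]
    p_hat <- mean(tr$uniqueness == "GC-unique")
    p <- cfg$unique_fraction[[f]]
    se <- sqrt(p * (1 - p) / nrow(tr))
    expect_lt(abs(p_hat - p), 3 * se + 1e-12)
  }
})

test_that("null cohorts (no unique types) are at chance level in CV", {
  cfg <- sim_config(donors_per_group = 6L, spectra_per_sample = c(10L, 14L),
                    fluids = "blood",
                    unique_fraction = c(blood = 0),
                    n_unique_subtypes = 0L, n_cross_fluid_types = 0L,
                    grid = sers_grid(553, 1581, 128L), seed = 44L)
  sim <- generate_cohort(cfg)
  pp <- preprocess_cohort(sim$cohorts$blood)
  y <- factor(pp$meta$group, levels = c("GC", "control"))
  rep <- cross_validate(pp$X, y, rounds = 10, seed = 3)
  expect_gt(rep$mean_accuracy, 0.35)
  expect_lt(rep$mean_accuracy, 0.65)
})

test_that("map scans follow the Gaussian-beam forward model", {
  g <- sers_grid(553, 1581, 257L)
  tpl <- make_subtype_template(seed = 86)
  # single emitter exactly at the lattice centre, no noise
  scan <- generate_map_scan(data.frame(x = 1, y = 1), tpl, beam_sigma = 0.42,
                            step = 0.1, extent = c(0, 2, 0, 2), noise_sd = 0,
                            grid = g)
  m <- build_intensity_map(scan, 1123, 8, baseline = "none")
  peak <- which(m$values == max(m$values), arr.ind = TRUE)
  expect_equal(m$xs[peak[1, "col"]], 1)
  expect_equal(m$ys[peak[1, "row"]], 1)

  # vanishing beam: only the emitter's lattice point sees signal
  tiny <- generate_map_scan(data.frame(x = 1, y = 1), tpl,
                            beam_sigma = 1e-4, step = 0.1,
                            extent = c(0, 2, 0, 2), noise_sd = 0, grid = g)
  tot <- rowSums(tiny$X)
  expect_equal(sum(tot > 1e-8 * max(tot)), 1L)

  # integrated map intensity ~ amplitude x 2 pi sigma^2 / step^2
  amp <- 1.7; sigma <- 0.3
  scan2 <- generate_map_scan(data.frame(x = 1, y = 1, amplitude = amp), tpl,
                             beam_sigma = sigma, step = 0.05,
                             extent = c(0, 2, 0, 2), noise_sd = 0, grid = g)
  w_tot <- sum(scan2$X[, which.max(render_template(tpl, g))]) /
    max(render_template(tpl, g))
  expect_equal(w_tot * 0.05^2, amp * 2 * pi * sigma^2, tolerance = 0.01)
})

test_that("raising the noise floor degrades end-to-end CV accuracy", {
  accs <- vapply(c(0.01, 0.7, 2), function(ns) {
    mean(vapply(1:5, function(s) {
      cfg <- sim_config(donors_per_group = 4L,
                        spectra_per_sample = c(6L, 8L), fluids = "blood",
                        unique_fraction = c(blood = 0.5), noise_sd = ns,
                        grid = sers_grid(553, 1581, 257L), seed = 100L + s)
      sim <- generate_cohort(cfg)
      pp <- preprocess_cohort(sim$cohorts$blood)
      y <- factor(pp$meta$group, levels = c("GC", "control"))
      cross_validate(pp$X, y, rounds = 4, seed = 1)$mean_accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) < 0))       # decreasing in expectation over seeds
  expect_gt(accs[1] - accs[3], 0.05)     # and clearly lower at high noise
})
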