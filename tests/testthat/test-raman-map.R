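map_grid <- function() sers_grid(553, 1581, 257L)

test_that("band intensity: zero, rectangle, and dense-quadrature oracle", {
  g <- map_grid()
  wn <- wavenumbers(g)
  expect_equal(band_intensity(rep(0, g$n), g, 1123), 0)

  # unit rectangle spanning exactly the window
  center <- wn[128]
  halfwidth <- 8 * (wn[2] - wn[1])
  y <- as.numeric(wn >= center - halfwidth & wn <= center + halfwidth)
  got <- band_intensity(y, g, center, halfwidth, baseline = "none")
  expect_equal(got, 2 * halfwidth, tolerance = 1e-12)

  # Lorentzian band vs dense numerical quadrature, on the native fine grid
  # (window endpoints aligned to grid points so both integrate the same span)
  g1 <- sers_grid()
  wn1 <- wavenumbers(g1)
  c1 <- wn1[714]                       # ~1270 cm^-1
  hw <- 8 * (wn1[2] - wn1[1])
  lor <- function(x) 0.9 / (1 + ((x - c1) / 6)^2)
  got <- band_intensity(lor(wn1), g1, c1, hw, baseline = "none")
  fine <- seq(c1 - hw, c1 + hw, length.out = 20001)
  want <- pracma::trapz(fine, lor(fine))
  expect_lt(abs(got - want) / want, 0.005)

  expect_error(band_intensity(lor(wn), g, 560, 10), "outside the grid")
})

test_that("intensity maps reflect the scan and commute with transposition", {
  g <- map_grid()
  tpl <- make_subtype_template(seed = 70)
  base <- render_template(tpl, g)
  pos <- expand.grid(x = seq(0, 0.4, by = 0.1), y = seq(0, 0.6, by = 0.1))
  X <- matrix(rep(base, nrow(pos)), nrow(pos), g$n, byrow = TRUE)
  scan <- map_scan(pos, X, g)
  m <- build_intensity_map(scan, 1123, 8, baseline = "none")
  expect_equal(dim(m$values), c(7L, 5L))    # rows = y, columns = x
  expect_lt(diff(range(m$values)), 1e-12)   # identical spectra -> constant map

  # single bright spectrum at a known position -> map maximum there
  bright <- which.min((pos$x - 0.2)^2 + (pos$y - 0.3)^2)
  X2 <- X; X2[bright, ] <- 5 * base
  m2 <- build_intensity_map(map_scan(pos, X2, g), 1123, 8, baseline = "none")
  peak <- which(m2$values == max(m2$values), arr.ind = TRUE)
  expect_equal(m2$xs[peak[1, "col"]], 0.2, tolerance = 1e-9)
  expect_equal(m2$ys[peak[1, "row"]], 0.3, tolerance = 1e-9)

  # lattice transposition: swap x/y in, transpose out
  pos_t <- data.frame(x = pos$y, y = pos$x)
  m_t <- build_intensity_map(map_scan(pos_t, X2, g), 1123, 8,
                             baseline = "none")
  expect_equal(m_t$values, t(m2$values))
})

test_that("hotspot localization: delta map, ties, emitter recovery", {
  g <- map_grid()
  tpl <- make_subtype_template(seed = 71)
  # delta map
  scan <- generate_map_scan(data.frame(x = 1.0, y = 0.7), tpl,
                            beam_sigma = 0.42, step = 0.1,
                            extent = c(0, 2, 0, 2), noise_sd = 0, grid = g)
  m <- build_intensity_map(scan, 1123, 8, baseline = "none")
  hs <- locate_hotspot(m)
  expect_equal(unname(hs), c(1.0, 0.7), tolerance = 1e-9)

  # two equal maxima: after zero-padded 3x3 smoothing each delta spreads to
  # a constant 3x3 block; the tie resolves to the lowest (row, column)
  mm <- m
  mm$values <- matrix(0, 5, 5)
  mm$values[1, 4] <- 1
  mm$values[4, 1] <- 1
  mm$xs <- seq(0, 0.4, 0.1); mm$ys <- seq(0, 0.4, 0.1)
  hs2 <- locate_hotspot(mm)
  expect_equal(unname(hs2), c(mm$xs[3], mm$ys[1]))

  mm$values <- matrix(1, 5, 5)
  expect_error(locate_hotspot(mm), "constant")
})

test_that("noisy emitters localize within one step width", {
  # native spectral grid: band integration averages the per-point noise
  g <- sers_grid()
  tpl <- make_subtype_template(seed = 72)
  peak_signal <- max(render_template(tpl, g))
  set.seed(73)
  hits <- 0L
  n_scenes <- 12L
  for (s in seq_len(n_scenes)) {
    x0 <- runif(1, 0.5, 1.5); y0 <- runif(1, 0.5, 1.5)
    scan <- generate_map_scan(data.frame(x = x0, y = y0), tpl,
                              beam_sigma = 0.42, step = 0.1,
                              extent = c(0, 2, 0, 2),
                              noise_sd = peak_signal / 10, grid = g)
    m <- build_intensity_map(scan, 1123, 8, baseline = "none")
    hs <- locate_hotspot(m)
    if (max(abs(c(hs[["x"]] - x0, hs[["y"]] - y0))) <= 0.1 + 1e-9) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, n_scenes - 1L)
})

test_that("colocalization: identity, negation, shared-emitter bands", {
  g <- map_grid()
  tpl <- make_subtype_template(seed = 74)
  scan <- generate_map_scan(data.frame(x = 1, y = 1), tpl, step = 0.1,
                            extent = c(0, 2, 0, 2), noise_sd = 0, grid = g)
  m <- build_intensity_map(scan, 1123, 8, baseline = "none")
  expect_equal(colocalization(list(a = m, b = m))$correlation, 1)
  neg <- m; neg$values <- -m$values
  expect_equal(colocalization(list(a = m, b = neg))$correlation, -1)

  # three marker-band maps from one emitter with independent noise
  set.seed(75)
  lib <- default_peak_library()
  tpl3 <- list(peaks = data.frame(center = c(1123, 1270, 1341),
                                  height = c(1, 1, 1), width = c(8, 8, 8)),
               type_id = "3band", uniqueness = "shared", cross_fluid = FALSE)
  class(tpl3) <- "sers_template"
  peak_signal <- max(render_template(tpl3, g))
  maps <- lapply(c(1123, 1270, 1341), function(b) {
    noisy <- generate_map_scan(data.frame(x = 1, y = 1), tpl3, step = 0.1,
                               extent = c(0, 2, 0, 2),
                               noise_sd = peak_signal / 10, grid = g)
    build_intensity_map(noisy, b, 8, baseline = "none")
  })
  cc <- colocalization(maps)
  expect_true(all(cc$correlation >= 0.7))
})
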