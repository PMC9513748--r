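# Small fixture builders shared across test files.

small_grid <- function(n = 64L) sers_grid(553, 1581, n)

# cohort with explicit intensities: one row of meta per spectrum
toy_cohort <- function(n_per_donor = 3L, donors = c(GC01 = "GC", C01 = "control"),
                       grid = small_grid(), fluid = "blood", seed = 1L) {
  set.seed(seed)
  meta <- do.call(rbind, lapply(names(donors), function(d) {
    data.frame(spectrum_id = sprintf("%s_%02d", d, seq_len(n_per_donor)),
               donor_id = d, group = donors[[d]], fluid = fluid,
               stringsAsFactors = FALSE)
  }))
  X <- matrix(runif(nrow(meta) * grid$n), nrow(meta), grid$n)
  sers_cohort(meta, X, grid)
}

# k well-separated synthetic classes: spherical Gaussians around distant
# centroids (feature space, not spectra)
separated_classes <- function(n_per_class = 20L, p = 30L, k = 2L,
                              sep = 10, sd = 1, seed = 1L) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(c) {
    center <- rep(0, p)
    center[c] <- sep
    sweep(matrix(rnorm(n_per_class * p, 0, sd), n_per_class, p), 2L, center,
          `+`)
  }))
  list(X = X, y = rep(paste0("class", seq_len(k)), each = n_per_class))
}

# render one clean spectrum per template for planted-subtype tests
planted_subtype_matrix <- function(n_types = 3L, n_per_type = 5L,
                                   grid = small_grid(128L), noise = 0.005,
                                   seed = 2L) {
  set.seed(seed)
  templates <- lapply(seq_len(n_types), function(i) make_subtype_template())
  X <- do.call(rbind, lapply(seq_len(n_types), function(i) {
    base <- render_template(templates[[i]], grid)
    do.call(rbind, lapply(seq_len(n_per_type), function(j) {
      base + rnorm(grid$n, 0, noise)
    }))
  }))
  rownames(X) <- sprintf("T%d_%d", rep(seq_len(n_types), each = n_per_type),
                         rep(seq_len(n_per_type), n_types))
  list(X = X, type = rep(seq_len(n_types), each = n_per_type),
       templates = templates)
}
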