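make_type_set <- function(templates, which_types, n_per_type, grid, noise,
                          prefix) {
  X <- NULL
  ids <- character(0)
  for (t in which_types) {
    base <- render_template(templates[[t]], grid)
    for (j in seq_len(n_per_type)) {
      X <- rbind(X, minmax_normalize(base + rnorm(grid$n, 0, noise)))
      ids <- c(ids, sprintf("%s_t%d_%d", prefix, t, j))
    }
  }
  list(X = X, ids = ids, type = rep(which_types, each = n_per_type))
}

test_that("PP type clustering: singleton, cut at infinity, planted types", {
  g <- small_grid(96L)
  one <- cluster_pp_types(matrix(runif(96), 1, 96), "only", cut_height = 1)
  expect_length(one$members, 1L)

  pl <- planted_subtype_matrix(n_types = 4L, n_per_type = 4L, grid = g)
  all_in_one <- cluster_pp_types(pl$X, rownames(pl$X), cut_height = Inf)
  expect_length(all_in_one$members, 1L)

  D <- pairwise_distances(pl$X)$values
  within <- max(D[outer(pl$type, pl$type, `==`)])
  between <- min(D[outer(pl$type, pl$type, `!=`)])
  ts <- cluster_pp_types(pl$X, rownames(pl$X), (within + between) / 2)
  expect_length(ts$members, 4L)
  # members of each recovered type share one planted label
  for (m in ts$members) {
    expect_length(unique(pl$type[match(m, rownames(pl$X))]), 1L)
  }
})

test_that("cross-fluid matching requires presence in all three fluids", {
  g <- small_grid(96L)
  set.seed(60)
  templates <- lapply(1:6, function(i) make_subtype_template())
  noise <- 0.01
  # types 1-3 exist everywhere; type 4 tissue+blood only; 5 tissue only;
  # 6 saliva only
  tis <- make_type_set(templates, c(1:3, 4, 5), 4, g, noise, "PT")
  blo <- make_type_set(templates, c(1:3, 4), 4, g, noise, "PB")
  sal <- make_type_set(templates, c(1:3, 6), 4, g, noise, "PS")

  cut <- 0.5
  t_tis <- cluster_pp_types(tis$X, tis$ids, cut)
  t_blo <- cluster_pp_types(blo$X, blo$ids, cut)
  t_sal <- cluster_pp_types(sal$X, sal$ids, cut)
  res <- match_types_across_fluids(t_tis, t_blo, t_sal, tau_track = cut)
  expect_length(res$types, 3L)
  for (tp in res$types) {
    planted <- unique(c(tis$type[match(tp$members$tissue, tis$ids)],
                        blo$type[match(tp$members$blood, blo$ids)],
                        sal$type[match(tp$members$saliva, sal$ids)]))
    expect_length(planted, 1L)    # one planted identity per matched type
    expect_true(planted %in% 1:3) # never a one- or two-fluid type
    expect_true(all(vapply(tp$members, length, integer(1)) >= 1L))
  }
})

test_that("matching is invariant to input order", {
  g <- small_grid(96L)
  set.seed(61)
  templates <- lapply(1:3, function(i) make_subtype_template())
  sets <- lapply(c("PT", "PB", "PS"), function(p) {
    make_type_set(templates, 1:3, 3, g, 0.01, p)
  })
  cut <- 0.5
  t1 <- lapply(sets, function(s) cluster_pp_types(s$X, s$ids, cut))
  res1 <- match_types_across_fluids(t1[[1]], t1[[2]], t1[[3]], cut)
  perm <- sample(nrow(sets[[1]]$X))
  t1p <- cluster_pp_types(sets[[1]]$X[perm, ], sets[[1]]$ids[perm], cut)
  res2 <- match_types_across_fluids(t1p, t1[[2]], t1[[3]], cut)
  expect_equal(length(res1$types), length(res2$types))
  sig <- function(res) {
    sort(vapply(res$types, function(tp) {
      paste(sort(unlist(tp$members)), collapse = ",")
    }, character(1)))
  }
  expect_identical(sig(res1), sig(res2))
})

test_that("members of matched types stay within the cut of their centroid", {
  g <- small_grid(96L)
  set.seed(62)
  templates <- lapply(1:3, function(i) make_subtype_template())
  sets <- lapply(c("PT", "PB", "PS"), function(p) {
    make_type_set(templates, 1:3, 4, g, 0.01, p)
  })
  cut <- 0.5
  tsets <- lapply(sets, function(s) cluster_pp_types(s$X, s$ids, cut))
  res <- match_types_across_fluids(tsets[[1]], tsets[[2]], tsets[[3]], cut)
  fluid_names <- c("tissue", "blood", "saliva")
  for (tp in res$types) {
    for (k in 1:3) {
      mem <- tp$members[[fluid_names[k]]]
      Xf <- sets[[k]]$X[match(mem, sets[[k]]$ids), , drop = FALSE]
      cen <- tp$centroids[[fluid_names[k]]]
      d <- sqrt(rowSums(sweep(Xf, 2, cen)^2))
      expect_true(all(d <= cut))
    }
  }
})

test_that("source distribution counts members per fluid", {
  g <- small_grid(96L)
  set.seed(63)
  templates <- list(make_subtype_template())
  tis <- make_type_set(templates, 1, 5, g, 0.01, "PT")
  blo <- make_type_set(templates, 1, 3, g, 0.01, "PB")
  sal <- make_type_set(templates, 1, 1, g, 0.01, "PS")
  cut <- 0.5
  res <- match_types_across_fluids(cluster_pp_types(tis$X, tis$ids, cut),
                                   cluster_pp_types(blo$X, blo$ids, cut),
                                   cluster_pp_types(sal$X, sal$ids, cut),
                                   cut)
  dist <- source_distribution(res)
  expect_equal(nrow(dist), 1L)
  expect_equal(dist$tissue, 5L)
  expect_equal(dist$blood, 3L)
  expect_equal(dist$saliva, 1L)
  expect_equal(dist$total, 9L)

  expect_warning(
    empty <- match_types_across_fluids(
      cluster_pp_types(tis$X, tis$ids, cut), NULL,
      cluster_pp_types(sal$X, sal$ids, cut), cut),
    "no PP types")
  expect_equal(nrow(source_distribution(empty)), 0L)
})
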