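toy <- matrix(c(0, 1, 9, 10), ncol = 1)

test_that("toy 1-D instance reaches the enumerated optimum from every initialization", {
  pairs <- utils::combn(4L, 2L)
  for (j in seq_len(ncol(pairs))) {
    fit <- hartigan_wong(toy, 2L, toy[pairs[, j], , drop = FALSE])
    expect_equal(fit$wcss, 1.0)
    expect_equal(fit$assignments[1], fit$assignments[2])
    expect_equal(fit$assignments[3], fit$assignments[4])
  }
  expect_equal(enum_min_wcss(toy, 2L), 1.0)
})

test_that("k = n puts every point in its own cluster with zero WCSS", {
  fit <- hartigan_wong(toy, 4L, toy)
  expect_equal(sort(fit$assignments), 1:4)
  expect_equal(fit$wcss, 0)
})

test_that("results satisfy the clustering_result invariants", {
  set.seed(21)
  x <- matrix(rnorm(50 * 3L), 50L)
  for (k in c(2L, 4L)) {
    set.seed(k)
    fit <- best_of_starts(x, k, n_starts = 5L)
    expect_setequal(unique(fit$assignments), seq_len(k))
    expect_equal(fit$wcss, wcss_of(x, fit$assignments),
                 tolerance = 1e-8)
    for (g in seq_len(k)) {
      expect_equal(fit$centroids[g, ],
                   colMeans(x[fit$assignments == g, , drop = FALSE]),
                   tolerance = 1e-8)
    }
    # descent vs the initialization's Voronoi partition is implied by
    # descent from any start; check against a fresh Voronoi baseline
    init <- x[seq_len(k), , drop = FALSE]
    fit2 <- hartigan_wong(x, k, init)
    voronoi <- apply(as.matrix(dist(rbind(init, x)))[-(1:k), 1:k, drop = FALSE],
                     1L, which.min)
    if (length(unique(voronoi)) == k) {
      expect_lte(fit2$wcss, wcss_of(x, voronoi) + 1e-8)
    }
  }
})

test_that("degenerate and invalid initializations are rejected", {
  expect_error(hartigan_wong(toy, 5L, rbind(toy, 3)), "k must satisfy")
  expect_error(hartigan_wong(toy, 2L, toy[c(1, 1), , drop = FALSE]),
               "duplicate initial centroids")
  expect_error(best_of_starts(matrix(c(1, 1, 1), ncol = 1), 2L),
               "fewer than k distinct rows")
})

test_that("the core agrees with an independent Hartigan-Wong implementation", {
  blobs <- make_blobs(n_per = 60L, seed = 13L)
  set.seed(1)
  mine <- best_of_starts(blobs$x, 2L, n_starts = 5L)
  ref <- stats::kmeans(blobs$x, 2L, nstart = 10L, algorithm = "Hartigan-Wong")
  expect_equal(mine$wcss, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(abs(cor(mine$assignments, ref$cluster)), 1)
})

test_that("WCSS is non-increasing in the number of starts under a fixed seed", {
  set.seed(31)
  x <- matrix(rnorm(40 * 2L), 40L)
  w <- vapply(c(1L, 3L, 10L), function(ns) {
    set.seed(99)
    best_of_starts(x, 3L, n_starts = ns)$wcss
  }, numeric(1))
  expect_true(all(diff(w) <= 1e-12))
})

test_that("permuting rows permutes assignments identically (fixed centroids)", {
  # Hartigan-Wong scans points in order, so exact row-permutation
  # equivariance is checked where the optimum is unique and reached from
  # any scan order: well-separated blobs.
  blobs <- make_blobs(n_per = 40L,
                      centers = rbind(c(0, 0), c(15, 0), c(0, 15)),
                      sd = 0.5, seed = 5L)
  x <- blobs$x
  init <- x[c(1L, 50L, 90L), ]
  base <- hartigan_wong(x, 3L, init)
  set.seed(6)
  perm <- sample(nrow(x))
  permuted <- hartigan_wong(x[perm, ], 3L, init)
  expect_equal(permuted$assignments, base$assignments[perm])
})

test_that("stability protocol records recurrence and extension correctly", {
  blobs <- make_blobs(n_per = 100L, seed = 17L)
  rep1 <- stability_protocol(blobs$x, 2L, n_runs = 20L,
                             recurrence_threshold = 10L,
                             extension_runs = 100L, n_starts = 5L, seed = 4L)
  expect_equal(rep1$min_count, 20L)
  expect_false(rep1$extended)
  expect_equal(rep1$n_runs_total, 20L)
  expect_equal(rep1$best$wcss, min(rep1$run_wcss))

  rep2 <- stability_protocol(blobs$x, 2L, n_runs = 1L,
                             recurrence_threshold = 0L, seed = 4L)
  expect_false(rep2$extended)
  expect_equal(rep2$n_runs_total, 1L)

  # adversarial flat data: the exact minimum never recurs, extension fires
  set.seed(8)
  flat <- matrix(1, 60L, 2L) + matrix(rnorm(120L, sd = 1e-3), 60L)
  rep3 <- stability_protocol(flat, 3L, n_runs = 10L,
                             recurrence_threshold = 10L,
                             extension_runs = 5L, n_starts = 2L, seed = 6L)
  expect_true(rep3$extended)
  expect_equal(rep3$n_runs_total, 15L)
})

test_that("protocol attains the enumerated global optimum on small instances", {
  set.seed(77)
  for (case in 1:10) {
    n <- sample(6:8, 1L)
    p <- sample(2:4, 1L)
    k <- sample(2:3, 1L)
    x <- matrix(rnorm(n * p), n, p)
    rep_k <- stability_protocol(x, k, n_runs = 5L, recurrence_threshold = 1L,
                                extension_runs = 3L, n_starts = 5L,
                                seed = case)
    expect_equal(rep_k$best$wcss, enum_min_wcss(x, k), tolerance = 1e-8)
  }
})

test_that("planted four-cluster structure is recovered at scale", {
  skip_if_not_installed("mclust")
  g <- generate_cohort(separated_preset(n = 2000L, seed = 23L))
  d <- build_design(g$cohort)
  rep4 <- stability_protocol(d, 4L, n_runs = 5L, recurrence_threshold = 2L,
                             extension_runs = 3L, n_starts = 5L, seed = 9L)
  ari <- mclust::adjustedRandIndex(rep4$best$assignments, g$labels)
  expect_gte(ari, 0.95)
})
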