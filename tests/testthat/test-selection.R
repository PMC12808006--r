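toy <- matrix(c(0, 1, 9, 10), ncol = 1)
toy_fit <- hartigan_wong(toy, 2L, toy[c(1L, 3L), , drop = FALSE])

test_that("Calinski-Harabasz matches the hand computation on the toy instance", {
  # grand mean 5, cluster means 0.5/9.5: BCSS = 81, WCSS = 1, CH = 81/(1/2)
  expect_equal(calinski_harabasz(toy, toy_fit), 162)
  expect_error(calinski_harabasz(toy, hartigan_wong(toy, 4L, toy)),
               "1 < k < n")
})

test_that("doubling every point leaves the BCSS/WCSS ratio invariant", {
  set.seed(2)
  x <- matrix(rnorm(30 * 2L), 30L)
  set.seed(3)
  fit <- best_of_starts(x, 3L, n_starts = 5L)
  x2 <- rbind(x, x)
  fit2 <- hartigan_wong(x2, 3L, fit$centroids)
  n <- nrow(x); n2 <- nrow(x2); k <- 3L
  ratio1 <- calinski_harabasz(x, fit) * (k - 1) / (n - k)
  ratio2 <- calinski_harabasz(x2, fit2) * (k - 1) / (n2 - k)
  expect_equal(ratio1, ratio2, tolerance = 1e-8)
})

test_that("coincident clusters yield an infinite CH score", {
  x <- matrix(rep(c(0, 0, 5, 5), each = 2L), ncol = 1)
  fit <- hartigan_wong(x, 2L, matrix(c(0, 5), ncol = 1))
  expect_equal(fit$wcss, 0)
  expect_equal(calinski_harabasz(x, fit), Inf)
})

test_that("simplified silhouette follows its centroid-based definition", {
  # toy: a = 0.5 everywhere; b = 9.5 (outer) or 8.5 (inner points)
  expected <- mean(c(9 / 9.5, 8 / 8.5, 8 / 8.5, 9 / 9.5))
  expect_equal(simplified_silhouette(toy, toy_fit), expected, tolerance = 1e-12)
  expect_equal(expected, 0.944272, tolerance = 1e-6)

  # a point exactly midway between its own and the nearest other centroid
  # scores 0 (b = a)
  mid <- list(k = 2L, assignments = 1L, centroids = matrix(c(0, 4), ncol = 1))
  expect_equal(simplified_silhouette(matrix(2, 1L, 1L), mid), 0)

  # points sitting on their own centroid with a distant alternative score ~1
  y <- matrix(c(0, 0, 100, 100), ncol = 1)
  yfit <- hartigan_wong(y, 2L, matrix(c(0, 100), ncol = 1))
  expect_equal(simplified_silhouette(y, yfit), 1)
})

test_that("simplified silhouette equals the full silhouette for singleton-tight clusters", {
  x <- rbind(matrix(0, 3L, 2L), matrix(5, 4L, 2L), matrix(c(9, 0), 3L, 2L,
                                                          byrow = TRUE))
  assign <- rep(1:3, c(3L, 4L, 3L))
  fit <- list(k = 3L, assignments = assign,
              centroids = rbind(c(0, 0), c(5, 5), c(9, 0)))
  expect_equal(simplified_silhouette(x, fit), full_silhouette(x, assign),
               tolerance = 1e-12)
})

test_that("indices are invariant to row order and cluster relabeling", {
  set.seed(4)
  x <- matrix(rnorm(40 * 2L), 40L)
  set.seed(5)
  fit <- best_of_starts(x, 3L, n_starts = 5L)
  ch <- calinski_harabasz(x, fit)
  sil <- simplified_silhouette(x, fit)

  perm <- sample(nrow(x))
  fitp <- list(k = 3L, assignments = fit$assignments[perm],
               centroids = fit$centroids)
  expect_equal(calinski_harabasz(x[perm, ], fitp), ch, tolerance = 1e-10)
  expect_equal(simplified_silhouette(x[perm, ], fitp), sil, tolerance = 1e-10)

  relab <- c(3L, 1L, 2L)
  fitr <- list(k = 3L, assignments = relab[fit$assignments],
               centroids = fit$centroids[order(relab), ])
  expect_equal(calinski_harabasz(x, fitr), ch, tolerance = 1e-10)
  expect_equal(simplified_silhouette(x, fitr), sil, tolerance = 1e-10)
})

test_that("selection curve finds planted blobs and degrades gracefully", {
  blobs <- make_blobs(n_per = 50L,
                      centers = rbind(c(0, 0), c(20, 0), c(0, 20), c(20, 20)),
                      sd = 0.5, seed = 6L)
  sc <- selection_curve(blobs$x, 2L, 6L, n_runs = 5L,
                        recurrence_threshold = 2L, extension_runs = 2L,
                        n_starts = 5L, seed = 10L)
  expect_equal(nrow(sc$curve), 5L)
  sk <- suggest_k(sc)
  expect_equal(unname(sk[["ch_index"]]), 4L)
  expect_equal(unname(sk[["silhouette"]]), 4L)
  expect_true(all(sc$curve$silhouette >= -1 & sc$curve$silhouette <= 1))
  expect_true(all(sc$curve$ch_index > 0))
  expect_true(all(diff(sc$curve$wcss) <= 1e-8))

  one <- selection_curve(blobs$x, 2L, 2L, n_runs = 2L,
                         recurrence_threshold = 0L, extension_runs = 0L,
                         n_starts = 2L, seed = 11L)
  expect_equal(nrow(one$curve), 1L)
})

test_that("WCSS at the global optimum is monotone in k on a small instance", {
  set.seed(12)
  x <- matrix(rnorm(8 * 2L), 8L)
  expect_gte(enum_min_wcss(x, 2L), enum_min_wcss(x, 3L))
  sc <- selection_curve(x, 2L, 3L, n_runs = 5L, recurrence_threshold = 1L,
                        extension_runs = 2L, n_starts = 5L, seed = 13L)
  expect_equal(sc$curve$wcss, c(enum_min_wcss(x, 2L), enum_min_wcss(x, 3L)),
               tolerance = 1e-8)
})
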