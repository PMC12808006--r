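#' Hartigan-Wong k-means from given initial centroids
#'
#' Runs the Hartigan-Wong transfer iteration: after an initial Voronoi
#' assignment of the starting centroids, single points move between clusters
#' whenever the size-adjusted gain `n_t d^2(x, c_t)/(n_t + 1)` is below the
#' removal cost `n_s d^2(x, c_s)/(n_s - 1)`, so every accepted move strictly
#' lowers the total WCSS. Iteration stops when a full pass makes no
#' transfer, or after `max_iter` passes (flagged as non-converged). Empty
#' clusters arising from the initial assignment are repaired by relocating
#' the point farthest from its own centroid; equidistant ties resolve to the
#' lower cluster index, so the result is deterministic given the centroids.
#'
#' @param design A `weighted_design` (or plain numeric matrix).
#' @param k Number of clusters (2 <= k <= n).
#' @param initial_centroids k x p matrix of distinct starting points.
#' @param max_iter Cap on transfer passes.
#' @return Object of class `clustering_result`: `k`, `assignments` (1..k,
#'   every label present), `centroids` (within-cluster means in the weighted
#'   space), `wcss`, `converged`, `n_iter`, `sizes`.
#' @export
hartigan_wong <- function(design, k, initial_centroids, max_iter = 100L) {
  x <- design_matrix(design)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n (k = ", k, ", n = ", n, ")")
  initial_centroids <- as.matrix(initial_centroids)
  if (nrow(initial_centroids) != k || ncol(initial_centroids) != ncol(x)) {
    stop("initial_centroids must be a k x p matrix")
  }
  if (anyDuplicated(initial_centroids)) stop("duplicate initial centroids")
  res <- hw_core(x, initial_centroids, as.integer(max_iter))
  structure(list(k = as.integer(k),
                 assignments = res$assignments,
                 centroids = res$centroids,
                 wcss = res$wcss,
                 converged = res$converged,
                 n_iter = res$n_iter,
                 sizes = res$sizes),
            class = "clustering_result")
}

design_matrix <- function(design) {
  if (inherits(design, "weighted_design")) design$matrix else as.matrix(design)
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k = %d, WCSS = %.6g, converged = %s (%d passes)\n",
              x$k, x$wcss, x$converged, x$n_iter))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Best of several random initializations
#'
#' Runs [hartigan_wong()] from `n_starts` independent initializations — each
#' k distinct observations sampled uniformly without replacement — and keeps
#' the solution with the lowest WCSS. Consumes the current RNG stream; seed
#' with `set.seed()` for reproducibility.
#'
#' @inheritParams hartigan_wong
#' @param n_starts Number of random initializations (protocol default 25).
#' @return The minimum-WCSS `clustering_result`.
#' @export
best_of_starts <- function(design, k, n_starts = 25L, max_iter = 100L) {
  x <- design_matrix(design)
  n <- nrow(x)
  if (nrow(unique(x)) < k) {
    stop("initialization error: fewer than k distinct rows")
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    idx <- sample.int(n, k)
    attempts <- 0L
    while (anyDuplicated(x[idx, , drop = FALSE]) && attempts < 100L) {
      idx <- sample.int(n, k)
      attempts <- attempts + 1L
    }
    if (anyDuplicated(x[idx, , drop = FALSE])) {
      # fall back to deterministic distinct rows
      idx <- which(!duplicated(x))[seq_len(k)]
    }
    fit <- hartigan_wong(design, k, x[idx, , drop = FALSE], max_iter = max_iter)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  best
}

#' Multi-run minimum-WCSS stability protocol
#'
#' The full clustering protocol: [best_of_starts()] (25 random starts, best
#' kept) is repeated `n_runs` times (default 200) and each run's minimum
#' WCSS recorded. If the overall minimum recurs in more than
#' `recurrence_threshold` runs (default 10), the minimum-WCSS clustering is
#' accepted; otherwise `extension_runs` additional runs (default 100) are
#' executed and the overall best kept. WCSS values within relative 1e-10 of
#' the minimum count as recurrences of it.
#'
#' Reproducibility: per-run sub-seeds are drawn up front from `seed`, so
#' individual runs are reproducible and independent of execution order.
#'
#' @inheritParams best_of_starts
#' @param n_runs Number of protocol runs.
#' @param recurrence_threshold Minimum-WCSS recurrence count that averts the
#'   extension.
#' @param extension_runs Additional runs when the minimum does not recur.
#' @param seed Master seed for the protocol.
#' @return Object of class `protocol_report`: `best` (minimum-WCSS
#'   `clustering_result`), `run_wcss`, `n_runs_total`, `min_count`,
#'   `extended`, `seed`.
#' @export
stability_protocol <- function(design, k, n_runs = 200L,
                               recurrence_threshold = 10L,
                               extension_runs = 100L,
                               n_starts = 25L, max_iter = 100L,
                               seed = 1L) {
  stopifnot(n_runs >= 1L, recurrence_threshold >= 0L, extension_runs >= 0L)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs + extension_runs)

  one_run <- function(i) {
    set.seed(run_seeds[i])
    best_of_starts(design, k, n_starts = n_starts, max_iter = max_iter)
  }
  runs <- lapply(seq_len(n_runs), one_run)
  run_wcss <- vapply(runs, function(r) r$wcss, numeric(1))
  min_w <- min(run_wcss)
  min_count <- sum(run_wcss <= min_w * (1 + 1e-10))
  extended <- FALSE
  if (min_count <= recurrence_threshold && extension_runs > 0L) {
    extended <- TRUE
    more <- lapply(n_runs + seq_len(extension_runs), one_run)
    runs <- c(runs, more)
    run_wcss <- c(run_wcss, vapply(more, function(r) r$wcss, numeric(1)))
    min_w <- min(run_wcss)
    min_count <- sum(run_wcss <= min_w * (1 + 1e-10))
  }
  best <- runs[[which.min(run_wcss)]]
  structure(list(best = best, run_wcss = run_wcss,
                 n_runs_total = length(run_wcss),
                 min_count = min_count, extended = extended,
                 seed = as.integer(seed)),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("<protocol_report> k = %d, best WCSS = %.6g over %d runs (min recurred %d times%s)\n",
              x$best$k, x$best$wcss, x$n_runs_total, x$min_count,
              if (x$extended) ", extension fired" else ""))
  invisible(x)
}

#' Recompute the WCSS of an assignment
#'
#' Independent of the clustering path: centroids are recomputed as
#' within-cluster means and the WCSS summed from scratch.
#'
#' @param design A `weighted_design` or matrix.
#' @param assignments Integer cluster labels.
#' @return Total within-cluster sum of squares.
#' @export
wcss_of <- function(design, assignments) {
  x <- design_matrix(design)
  stopifnot(length(assignments) == nrow(x))
  tot <- 0
  for (g in unique(assignments)) {
    xs <- x[assignments == g, , drop = FALSE]
    ctr <- colMeans(xs)
    tot <- tot + sum(sweep(xs, 2L, ctr, "-")^2)
  }
  tot
}
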