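#' Calinski-Harabasz index of a clustering
#'
#' `(BCSS/(k-1)) / (WCSS/(n-k))` with `BCSS = sum_g n_g ||c_g - c_bar||^2`
#' about the grand centroid, computed in the same weighted space as the
#' clustering. Higher is better. A zero WCSS (all points coincide with
#' their centroids) yields `Inf`.
#'
#' @param design A `weighted_design` or matrix.
#' @param result A `clustering_result` on that design.
#' @return The index value.
#' @export
calinski_harabasz <- function(design, result) {
  x <- design_matrix(design)
  n <- nrow(x)
  k <- result$k
  if (k <= 1 || k >= n) stop("Calinski-Harabasz requires 1 < k < n")
  grand <- colMeans(x)
  sizes <- tabulate(result$assignments, nbins = k)
  bcss <- sum(sizes * rowSums(sweep(result$centroids, 2L, grand, "-")^2))
  wcss <- wcss_of(design, result$assignments)
  if (wcss == 0) return(Inf)
  (bcss / (k - 1)) / (wcss / (n - k))
}

#' Mean simplified silhouette of a clustering
#'
#' The centroid-based silhouette: per point, `a_i` is the Euclidean distance
#' to its own centroid and `b_i` the minimum distance to any other centroid;
#' `s_i = (b_i - a_i) / max(a_i, b_i)` (0 when both are 0). Using centroid
#' rather than mean pairwise distances keeps the score linear in n, which is
#' what makes it usable on registry-scale cohorts.
#'
#' @inheritParams calinski_harabasz
#' @return Mean of `s_i`, in \[-1, 1\].
#' @export
simplified_silhouette <- function(design, result) {
  x <- design_matrix(design)
  k <- result$k
  if (k < 2) stop("silhouette requires k >= 2")
  # n x k matrix of squared distances to each centroid
  cc <- rowSums(result$centroids^2)
  d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(result$centroids) +
    outer(rep(1, nrow(x)), cc)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  idx <- cbind(seq_len(nrow(x)), result$assignments)
  a <- d[idx]
  d[idx] <- Inf
  b <- apply(d, 1L, min)
  s <- ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b))
  mean(s)
}

#' Cluster-number selection curve
#'
#' Runs the stability protocol for each k in `k_min..k_max` and records the
#' minimum WCSS (elbow curve), the Calinski-Harabasz index and the mean
#' simplified silhouette of the best clustering, all in the weighted space.
#' The curve is reported for judgment, not auto-thresholded: the published
#' analysis combined these statistics with model simplicity and clinical
#' interpretability. [suggest_k()] reports the argmax of each index as a
#' convenience.
#'
#' @param design A `weighted_design`.
#' @param k_min,k_max Range of cluster counts (default 2..20).
#' @param n_runs,recurrence_threshold,extension_runs,n_starts,max_iter
#'   Protocol parameters, see [stability_protocol()].
#' @param seed Master seed; per-k sub-seeds are derived from it.
#' @return Object of class `selection_curve`: data frame `curve` (k, wcss,
#'   ch_index, silhouette, min_count, extended) and list `reports`.
#' @export
selection_curve <- function(design, k_min = 2L, k_max = 20L,
                            n_runs = 200L, recurrence_threshold = 10L,
                            extension_runs = 100L, n_starts = 25L,
                            max_iter = 100L, seed = 1L) {
  n <- nrow(design_matrix(design))
  if (!(2 <= k_min && k_min <= k_max && k_max < n)) {
    stop("need 2 <= k_min <= k_max < n")
  }
  ks <- seq.int(k_min, k_max)
  set.seed(seed)
  k_seeds <- sample.int(.Machine$integer.max - 1L, length(ks))
  reports <- vector("list", length(ks))
  rows <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    rep_i <- stability_protocol(design, ks[i], n_runs = n_runs,
                                recurrence_threshold = recurrence_threshold,
                                extension_runs = extension_runs,
                                n_starts = n_starts, max_iter = max_iter,
                                seed = k_seeds[i])
    reports[[i]] <- rep_i
    rows[[i]] <- data.frame(
      k = ks[i], wcss = rep_i$best$wcss,
      ch_index = calinski_harabasz(design, rep_i$best),
      silhouette = simplified_silhouette(design, rep_i$best),
      min_count = rep_i$min_count, extended = rep_i$extended
    )
  }
  curve <- do.call(rbind, rows)
  if (is.unsorted(-curve$wcss)) {
    warning("WCSS is not monotone non-increasing in k; some k may be stuck in local optima")
  }
  structure(list(curve = curve, reports = reports), class = "selection_curve")
}

#' Per-index suggested k
#'
#' @param sc A `selection_curve`.
#' @return Named integer vector: k at the Calinski-Harabasz argmax and at
#'   the silhouette argmax.
#' @export
suggest_k <- function(sc) {
  stopifnot(inherits(sc, "selection_curve"))
  c(ch_index = sc$curve$k[which.max(sc$curve$ch_index)],
    silhouette = sc$curve$k[which.max(sc$curve$silhouette)])
}

#' Plot the selection curve (elbow + validity indices)
#'
#' @param x A `selection_curve`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.selection_curve <- function(x, ...) {
  cv <- x$curve
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(cv$k, cv$wcss, type = "b", xlab = "k", ylab = "minimum WCSS",
                 main = "Elbow")
  graphics::plot(cv$k, cv$ch_index, type = "b", xlab = "k",
                 ylab = "Calinski-Harabasz", main = "CH index")
  graphics::plot(cv$k, cv$silhouette, type = "b", xlab = "k",
                 ylab = "simplified silhouette", main = "Silhouette")
  invisible(x)
}

#' @export
print.selection_curve <- function(x, ...) {
  cat("<selection_curve>\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}
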