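#' Optimal cluster-label matching between two partitions
#'
#' Finds the relabeling of `other` that maximizes the total diagonal overlap
#' with `base`, by maximum-weight perfect matching (Hungarian-style optimal
#' assignment) on the k x k contingency matrix. If the two solutions use
#' different numbers of labels the contingency matrix is padded with empty
#' clusters.
#'
#' @param base_assignments,other_assignments Integer label vectors of equal
#'   length, labels in 1..k.
#' @param k Number of clusters (default: largest label seen).
#' @return Integer permutation `perm` of 1..k: base cluster `b` is matched
#'   to `other` cluster `perm[b]`.
#' @export
match_clusters <- function(base_assignments, other_assignments,
                           k = max(base_assignments, other_assignments)) {
  if (length(base_assignments) != length(other_assignments)) {
    stop("assignment vectors must have equal length")
  }
  if (any(base_assignments < 1 | base_assignments > k) ||
      any(other_assignments < 1 | other_assignments > k)) {
    stop("cluster label out of range 1..k")
  }
  cm <- table(factor(base_assignments, levels = seq_len(k)),
              factor(other_assignments, levels = seq_len(k)))
  cm <- matrix(as.integer(cm), k, k)
  # +1 keeps every edge present (zero-overlap pairs included) without
  # changing the argmax: every perfect matching gains exactly k.
  g <- igraph::graph_from_biadjacency_matrix(cm + 1L, weighted = TRUE)
  m <- igraph::max_bipartite_match(g)
  perm <- m$matching[seq_len(k)] - k
  as.integer(perm)
}

#' Matched confusion matrix and diagonal agreement
#'
#' @inheritParams match_clusters
#' @return List: `confusion` (base clusters x matched perturbed clusters),
#'   `agreement` (trace/n), `perm` (the matching permutation).
#' @export
matched_confusion <- function(base_assignments, other_assignments,
                              k = max(base_assignments, other_assignments)) {
  perm <- match_clusters(base_assignments, other_assignments, k)
  cm <- table(factor(base_assignments, levels = seq_len(k)),
              factor(other_assignments, levels = seq_len(k)))
  cm <- matrix(as.integer(cm), k, k)[, perm, drop = FALSE]
  dimnames(cm) <- list(base = seq_len(k), matched = perm)
  list(confusion = cm,
       agreement = sum(diag(cm)) / length(base_assignments),
       perm = perm)
}

#' Weight-perturbation sensitivity analysis
#'
#' Re-runs the full clustering protocol with the utilization weight scaled
#' by each factor (default 0.5 and 2 — the published perturbation limits),
#' optimally matches each perturbed solution to the base solution, and
#' reports the matched confusion matrix and the diagonal agreement. The
#' perturbed runs reuse the protocol parameters with fresh seeded
#' substreams. The goal is robustness assessment, not optimization of the
#' weighting scheme.
#'
#' @param x A `cohort_matrix`, or a list with numeric matrices `conditions`
#'   and `utilization` (generic schema, used by constructed fixtures).
#' @param k Number of clusters.
#' @param factors Weight multipliers to probe.
#' @param base Optional `protocol_report` of the base (factor 1) solution;
#'   computed if missing.
#' @param n_runs,recurrence_threshold,extension_runs,n_starts,max_iter
#'   Protocol parameters, see [stability_protocol()].
#' @param seed Master seed; sub-seeds per factor are derived from it.
#' @return Object of class `sensitivity_report`: `factors`, `base`
#'   (protocol report), and per factor a list with `confusion`, `agreement`,
#'   `agreement_pct` (1 decimal), `perm`, `report`.
#' @export
weight_sensitivity <- function(x, k, factors = c(0.5, 2),
                               base = NULL,
                               n_runs = 20L, recurrence_threshold = 10L,
                               extension_runs = 10L, n_starts = 5L,
                               max_iter = 100L, seed = 1L) {
  make_design <- function(f) {
    if (inherits(x, "cohort_matrix")) {
      build_design(x, weight_factor = f)
    } else {
      build_design_matrices(x$conditions, x$utilization, weight_factor = f)
    }
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(factors) + 1L)
  if (is.null(base)) {
    base <- stability_protocol(make_design(1), k, n_runs = n_runs,
                               recurrence_threshold = recurrence_threshold,
                               extension_runs = extension_runs,
                               n_starts = n_starts, max_iter = max_iter,
                               seed = sub_seeds[length(factors) + 1L])
  }
  per_factor <- lapply(seq_along(factors), function(i) {
    rep_f <- stability_protocol(make_design(factors[i]), k, n_runs = n_runs,
                                recurrence_threshold = recurrence_threshold,
                                extension_runs = extension_runs,
                                n_starts = n_starts, max_iter = max_iter,
                                seed = sub_seeds[i])
    mc <- matched_confusion(base$best$assignments, rep_f$best$assignments, k)
    c(mc, list(agreement_pct = round_half_up(100 * mc$agreement, 1),
               report = rep_f))
  })
  names(per_factor) <- paste0("factor_", factors)
  structure(list(factors = factors, base = base, results = per_factor),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> base k =", x$base$best$k, "\n")
  for (i in seq_along(x$factors)) {
    r <- x$results[[i]]
    cat(sprintf("  factor %.2f: diagonal agreement %.1f%%\n",
                x$factors[i], r$agreement_pct))
  }
  invisible(x)
}
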