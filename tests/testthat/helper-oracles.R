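# Independent oracles used across tests. These deliberately avoid the code
# paths they check: enumeration instead of iteration, dictionaries instead
# of ranking logic, mean-pairwise silhouette instead of the centroid form.

# Global minimum WCSS by exhaustive enumeration of all assignments of n
# points to k non-empty clusters. Feasible for k^n up to ~1e5.
enum_min_wcss <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    if (length(unique(a)) < k) next
    w <- 0
    for (g in seq_len(k)) {
      xs <- x[a == g, , drop = FALSE]
      w <- w + sum(sweep(xs, 2L, colMeans(xs), "-")^2)
    }
    if (w < best) best <- w
  }
  best
}

# Brute-force exact portfolio counts: persons' condition sets as sorted
# label strings, counted in a dictionary, no ranking machinery.
brute_portfolio_counts <- function(label_sets, m) {
  sizes <- vapply(label_sets, length, integer(1))
  keys <- vapply(label_sets[sizes == m],
                 function(s) paste(sort(s), collapse = " + "), character(1))
  if (!length(keys)) return(integer(0))
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

# Optimal diagonal overlap by explicit enumeration of all k! permutations.
enum_best_diagonal <- function(cm) {
  k <- nrow(cm)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == k), ,
                 drop = FALSE]
  scores <- apply(perms, 1L, function(p) sum(cm[cbind(seq_len(k), p)]))
  list(score = max(scores), perm = perms[which.max(scores), ])
}

# Full (mean-pairwise) silhouette, brute force.
full_silhouette <- function(x, assign) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assign == assign[i])
    a <- if (length(own) > 1L) mean(d[i, setdiff(own, i)]) else 0
    b <- min(vapply(setdiff(unique(assign), assign[i]), function(g) {
      mean(d[i, assign == g])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}
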