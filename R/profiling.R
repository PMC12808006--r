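#' Round half away from zero
#'
#' Printed-table reproduction rule: `round()` in R rounds half to even;
#' published tables round half up. O/E ratios and percentages are always
#' computed from unrounded values first and only rounded for display.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Observed/expected prevalence ratio
#'
#' Cluster prevalence of a condition divided by its prevalence in the whole
#' multimorbid population; values above 1 mark over-representation.
#'
#' @param cluster_prev Cluster prevalence (fraction or percent).
#' @param overall_prev Overall prevalence on the same scale (> 0).
#' @return O/E ratio(s); `NA` where the overall prevalence is 0.
#' @export
oe_ratio <- function(cluster_prev, overall_prev) {
  ifelse(overall_prev > 0, cluster_prev / overall_prev, NA_real_)
}

#' Percent increase corresponding to an O/E ratio
#'
#' @param oe O/E ratio(s).
#' @return `(oe - 1) * 100`.
#' @export
pct_increase <- function(oe) (oe - 1) * 100

check_alignment <- function(cohort, assignments) {
  if (length(assignments) != cohort_size(cohort)) {
    stop("assignments length (", length(assignments),
         ") does not match cohort size (", cohort_size(cohort), ")")
  }
  as.integer(assignments)
}

#' Per-cluster condition prevalence and O/E table
#'
#' Prevalences are within-group means of the binary condition flags; O/E is
#' the cluster prevalence over the overall prevalence, computed from
#' unrounded fractions; the percent increase is `(O/E - 1) * 100` and the
#' over-expected flag marks O/E > 1.
#'
#' @param cohort A `cohort_matrix`.
#' @param assignments Cluster labels aligned with the cohort rows.
#' @return Data frame with one row per (condition, cluster): `condition`,
#'   `cluster`, `prevalence`, `overall_prevalence` (fractions), `oe`,
#'   `pct_increase`, `over_expected`.
#' @export
prevalence_and_oe <- function(cohort, assignments) {
  assignments <- check_alignment(cohort, assignments)
  clusters <- sort(unique(assignments))
  overall <- colMeans(cohort$conditions)
  rows <- lapply(clusters, function(g) {
    prev <- colMeans(cohort$conditions[assignments == g, , drop = FALSE])
    oe <- oe_ratio(prev, overall)
    data.frame(condition = colnames(cohort$conditions), cluster = g,
               prevalence = unname(prev), overall_prevalence = unname(overall),
               oe = unname(oe), pct_increase = unname(pct_increase(oe)),
               over_expected = unname(!is.na(oe) & oe > 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact chronic-condition portfolios per cluster
#'
#' A portfolio of size m counts persons holding exactly that set of m
#' conditions and no others. With `include_risk_factors = FALSE` the three
#' risk factors (hypertension, high cholesterol, obesity) are dropped from
#' every person's set before cardinality is determined, so a person may fall
#' below two remaining conditions and then contributes to no portfolio.
#' Rankings are by count descending, ties broken lexicographically by the
#' sorted condition names; percentages use the cluster size as denominator.
#'
#' @param cohort A `cohort_matrix`.
#' @param assignments Cluster labels aligned with the cohort rows.
#' @param sizes Portfolio sizes to tabulate (default 2:4).
#' @param include_risk_factors Keep the risk-factor conditions in the sets.
#' @param top_n Entries reported per (cluster, size).
#' @return Data frame: `cluster`, `size`, `rank`, `conditions` (labels
#'   joined by " + "), `count`, `pct` (of cluster size, in percent).
#' @export
portfolios <- function(cohort, assignments, sizes = 2:4,
                       include_risk_factors = TRUE, top_n = 5L) {
  assignments <- check_alignment(cohort, assignments)
  stopifnot(top_n >= 1L)
  cond <- cohort$conditions
  keep <- if (include_risk_factors) rep(TRUE, ncol(cond)) else !cohort$catalog$risk_factor
  cond <- cond[, keep, drop = FALSE]
  labels <- cohort$catalog$label[keep]

  # per person: sorted label set and its cardinality
  sets <- apply(cond == 1, 1L, function(r) paste(sort(labels[r]), collapse = " + "))
  card <- rowSums(cond)

  out <- list()
  for (g in sort(unique(assignments))) {
    in_g <- assignments == g
    n_g <- sum(in_g)
    for (m in sizes) {
      sel <- in_g & card == m
      if (!any(sel)) next
      tab <- table(sets[sel])
      ord <- order(-as.integer(tab), names(tab))
      tab <- tab[ord][seq_len(min(top_n, length(tab)))]
      out[[length(out) + 1L]] <- data.frame(
        cluster = g, size = m, rank = seq_along(tab),
        conditions = names(tab), count = as.integer(tab),
        pct = 100 * as.integer(tab) / n_g, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster = integer(0), size = integer(0), rank = integer(0),
               conditions = character(0), count = integer(0), pct = numeric(0))
  attr(res, "include_risk_factors") <- include_risk_factors
  rownames(res) <- NULL
  res
}

#' Sociodemographic distributions per cluster, with extreme annotations
#'
#' Percent of each category within each cluster; per (variable, category)
#' row the lowest and highest cluster are flagged, mirroring the published
#' table layout. If the cohort carries a numeric `age` column, a mean-age
#' row (variable `"age"`, category `"mean"`, value in years not percent) is
#' appended.
#'
#' @param cohort A `cohort_matrix`.
#' @param assignments Cluster labels aligned with the cohort rows.
#' @return Data frame: `variable`, `category`, `cluster`, `pct`,
#'   `is_lowest`, `is_highest`.
#' @export
sociodemographic_profile <- function(cohort, assignments) {
  assignments <- check_alignment(cohort, assignments)
  clusters <- sort(unique(assignments))
  out <- list()
  for (f in sociodemo_fields()) {
    v <- cohort$sociodemo[[f]]
    cats <- sort(unique(v))
    pct <- sapply(clusters, function(g) {
      100 * as.vector(prop.table(table(factor(v[assignments == g], levels = cats))))
    })
    pct <- matrix(pct, nrow = length(cats))
    for (i in seq_along(cats)) {
      lo <- which.min(pct[i, ])
      hi <- which.max(pct[i, ])
      out[[length(out) + 1L]] <- data.frame(
        variable = f, category = cats[i], cluster = clusters,
        pct = pct[i, ],
        is_lowest = seq_along(clusters) == lo,
        is_highest = seq_along(clusters) == hi,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if ("age" %in% names(cohort$sociodemo)) {
    means <- vapply(clusters, function(g) {
      mean(cohort$sociodemo$age[assignments == g])
    }, numeric(1))
    res <- rbind(res, data.frame(
      variable = "age", category = "mean", cluster = clusters, pct = means,
      is_lowest = seq_along(clusters) == which.min(means),
      is_highest = seq_along(clusters) == which.max(means),
      stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res
}

#' Utilization means and condition-count distribution per cluster
#'
#' Arithmetic means of the 7 raw (unstandardized) utilization variables per
#' cluster, the distribution of condition counts binned 2..9 and ">=10"
#' (a "<2" bin appears only if multimorbidity was not enforced), and the
#' mean condition count per cluster.
#'
#' @param cohort A `cohort_matrix`.
#' @param assignments Cluster labels aligned with the cohort rows.
#' @return List with data frames `utilization_means` (`cluster`, `variable`,
#'   `mean`), `condition_counts` (`cluster`, `bin`, `pct`) and
#'   `mean_conditions` (`cluster`, `mean`).
#' @export
utilization_and_counts <- function(cohort, assignments) {
  assignments <- check_alignment(cohort, assignments)
  clusters <- sort(unique(assignments))
  csum <- rowSums(cohort$conditions)
  bins <- c(if (any(csum < 2)) "<2", as.character(2:9), ">=10")
  bin_of <- function(s) ifelse(s < 2, "<2", ifelse(s >= 10, ">=10", as.character(s)))

  um <- do.call(rbind, lapply(clusters, function(g) {
    data.frame(cluster = g, variable = cohort$util_schema,
               mean = unname(colMeans(cohort$utilization[assignments == g, , drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  cc <- do.call(rbind, lapply(clusters, function(g) {
    b <- factor(bin_of(csum[assignments == g]), levels = bins)
    data.frame(cluster = g, bin = bins,
               pct = 100 * as.vector(prop.table(table(b))),
               stringsAsFactors = FALSE)
  }))
  mc <- data.frame(cluster = clusters,
                   mean = vapply(clusters, function(g) mean(csum[assignments == g]),
                                 numeric(1)))
  list(utilization_means = um, condition_counts = cc, mean_conditions = mc)
}

#' Full cluster profile bundle
#'
#' Assembles everything the published cluster characterization reports:
#' cluster sizes and shares, utilization means, condition-count
#' distribution, sociodemographic distributions with lowest/highest
#' annotations, the prevalence/O-E table, and exact condition portfolios in
#' both variants (risk factors included and excluded).
#'
#' @inheritParams prevalence_and_oe
#' @param portfolio_sizes Portfolio sizes, default 2:4.
#' @param top_n Portfolio entries per (cluster, size).
#' @return Object of class `cluster_profiles`.
#' @export
cluster_profiles <- function(cohort, assignments, portfolio_sizes = 2:4,
                             top_n = 5L) {
  assignments <- check_alignment(cohort, assignments)
  clusters <- sort(unique(assignments))
  sizes <- vapply(clusters, function(g) sum(assignments == g), integer(1))
  uc <- utilization_and_counts(cohort, assignments)
  structure(list(
    sizes = data.frame(cluster = clusters, n = sizes,
                       pct = 100 * sizes / sum(sizes)),
    utilization_means = uc$utilization_means,
    condition_counts = uc$condition_counts,
    mean_conditions = uc$mean_conditions,
    sociodemo = sociodemographic_profile(cohort, assignments),
    prevalence = prevalence_and_oe(cohort, assignments),
    portfolios_with_rf = portfolios(cohort, assignments, portfolio_sizes,
                                    include_risk_factors = TRUE, top_n = top_n),
    portfolios_without_rf = portfolios(cohort, assignments, portfolio_sizes,
                                       include_risk_factors = FALSE, top_n = top_n)
  ), class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat("<cluster_profiles>\n")
  cat("  cluster sizes:\n")
  print(transform(x$sizes, pct = round_half_up(pct, 2)), row.names = FALSE)
  top <- x$prevalence[x$prevalence$over_expected, ]
  top <- top[order(-top$oe), ][seq_len(min(5L, nrow(top))), ]
  cat("  top over-expected conditions (O/E):\n")
  print(data.frame(condition = top$condition, cluster = top$cluster,
                   oe = round_half_up(top$oe, 2)), row.names = FALSE)
  invisible(x)
}
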