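#' Specification of one planted cluster
#'
#' Defines the statistical profile of a cluster in a synthetic registry
#' cohort: a mixing proportion, marginal Bernoulli prevalences for the 33
#' conditions, negative-binomial utilization (mean/dispersion, with
#' dispersion the NB size parameter: variance = mu + mu^2/dispersion), and a
#' categorical distribution per sociodemographic field.
#'
#' Conditions are independent Bernoulli within a cluster; cross-condition
#' correlation in the cohort arises only through cluster membership.
#'
#' @param mixing_proportion Probability of membership.
#' @param condition_prevalence Named (or catalog-ordered) vector of 33
#'   prevalences in \[0,1\].
#' @param utilization_mean Vector of 7 non-negative means (schema order).
#' @param utilization_dispersion Vector of 7 positive NB size parameters
#'   (recycled from length 1).
#' @param sociodemo_dists Named list: per sociodemographic field, a named
#'   probability vector over its categories (normalized to sum to 1).
#' @param mean_age Optional mean for an auxiliary numeric age column.
#' @return Object of class `cluster_spec`.
#' @export
cluster_spec <- function(mixing_proportion, condition_prevalence,
                         utilization_mean, utilization_dispersion = 1,
                         sociodemo_dists = default_sociodemo_dists(),
                         mean_age = NULL) {
  stopifnot(length(mixing_proportion) == 1L,
            mixing_proportion >= 0, mixing_proportion <= 1)
  if (length(condition_prevalence) != 33L) {
    stop("condition_prevalence must have 33 entries")
  }
  if (any(condition_prevalence < 0 | condition_prevalence > 1)) {
    stop("condition prevalences must lie in [0, 1]")
  }
  if (length(utilization_mean) != 7L || any(utilization_mean < 0)) {
    stop("utilization_mean must be 7 non-negative values")
  }
  utilization_dispersion <- rep_len(utilization_dispersion, 7L)
  if (any(utilization_dispersion <= 0)) stop("dispersion must be positive")
  sociodemo_dists <- lapply(sociodemo_dists, function(p) {
    if (any(p < 0)) stop("sociodemographic probabilities must be non-negative")
    p / sum(p)
  })
  if (!setequal(names(sociodemo_dists), sociodemo_fields())) {
    stop("sociodemo_dists must cover exactly the sociodemographic fields")
  }
  structure(list(mixing_proportion = mixing_proportion,
                 condition_prevalence = condition_prevalence,
                 utilization_mean = utilization_mean,
                 utilization_dispersion = utilization_dispersion,
                 sociodemo_dists = sociodemo_dists[sociodemo_fields()],
                 mean_age = mean_age),
            class = "cluster_spec")
}

#' Uniform sociodemographic distributions (generator fallback)
#'
#' @return Named list of uniform categorical distributions over the schema
#'   categories of each sociodemographic field.
#' @export
default_sociodemo_dists <- function() {
  cats <- list(
    age_band = c("lt_16", "17_24", "25_44", "45_64", "65_84", "gt_85"),
    sex = c("male", "female"),
    family_type = c("registered_partnership", "cohabiting_couple",
                    "co_residing_couple", "married_couple", "single"),
    region = c("north_denmark", "central_denmark", "southern_denmark",
               "capital", "zealand"),
    employment = c("self_employed", "employee", "unemployed", "in_education",
                   "early_retirement", "retired", "social_assistance",
                   "unknown"),
    education = c("none", "short", "medium", "long", "unknown"),
    income_quartile = c("q1", "q2", "q3", "q4")
  )
  lapply(cats, function(x) stats::setNames(rep(1 / length(x), length(x)), x))
}

#' Specification of a synthetic registry cohort
#'
#' @param n Cohort size.
#' @param clusters List of [cluster_spec()] objects; mixing proportions must
#'   sum to 1 (within 1e-9).
#' @param seed Integer RNG seed; identical seeds give bit-identical cohorts.
#' @param enforce_multimorbidity Redraw condition vectors until every person
#'   has >= 2 conditions.
#' @param max_rejections Per-person cap on condition redraws.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(n, clusters, seed = 1L,
                           enforce_multimorbidity = TRUE,
                           max_rejections = 1000L) {
  stopifnot(n >= length(clusters), length(clusters) >= 1L)
  mix <- vapply(clusters, function(cl) cl$mixing_proportion, numeric(1))
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("mixing proportions must sum to 1 (got ", format(sum(mix)), ")")
  }
  structure(list(n = as.integer(n), clusters = clusters,
                 seed = as.integer(seed),
                 enforce_multimorbidity = isTRUE(enforce_multimorbidity),
                 max_rejections = as.integer(max_rejections)),
            class = "generator_spec")
}

#' Generate a synthetic registry cohort with planted clusters
#'
#' Each person's cluster is drawn from the mixing proportions; conditions are
#' independent Bernoulli draws at the cluster's prevalences; utilization
#' counts are negative binomial (registry utilization is overdispersed);
#' sociodemographics are drawn from the cluster's categorical distributions.
#' Under multimorbidity enforcement, persons with fewer than two conditions
#' have their condition vector (only) redrawn, which preserves the mixing
#' proportions and utilization distributions exactly.
#'
#' @param spec A [generator_spec()].
#' @return List with elements `cohort` (a `cohort_matrix`) and `labels`
#'   (integer vector of true cluster indices).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n
  k <- length(spec$clusters)
  catalog <- condition_catalog()
  schema <- utilization_schema()

  mix <- vapply(spec$clusters, function(cl) cl$mixing_proportion, numeric(1))
  z <- sample.int(k, n, replace = TRUE, prob = mix)

  prev <- do.call(rbind, lapply(spec$clusters, function(cl) {
    p <- cl$condition_prevalence
    if (!is.null(names(p))) p <- p[catalog$name]
    unname(p)
  }))
  cond <- matrix(0, n, 33L, dimnames = list(NULL, catalog$name))
  for (j in seq_len(33L)) {
    cond[, j] <- stats::rbinom(n, 1L, prev[z, j])
  }

  if (spec$enforce_multimorbidity) {
    attempts <- 0L
    repeat {
      low <- which(rowSums(cond) < 2)
      if (!length(low)) break
      attempts <- attempts + 1L
      if (attempts > spec$max_rejections) {
        stop("multimorbidity rejection budget exhausted for cluster(s): ",
             paste(sort(unique(z[low])), collapse = ", "))
      }
      for (j in seq_len(33L)) {
        cond[low, j] <- stats::rbinom(length(low), 1L, prev[z[low], j])
      }
    }
  }

  mu <- do.call(rbind, lapply(spec$clusters, function(cl) cl$utilization_mean))
  th <- do.call(rbind, lapply(spec$clusters, function(cl) cl$utilization_dispersion))
  util <- matrix(0, n, 7L, dimnames = list(NULL, schema))
  for (j in seq_len(7L)) {
    m_j <- mu[z, j]
    pos <- m_j > 0
    if (any(pos)) {
      util[pos, j] <- stats::rnbinom(sum(pos), size = th[z[pos], j], mu = m_j[pos])
    }
  }

  sd_df <- as.data.frame(lapply(stats::setNames(nm = sociodemo_fields()), function(f) {
    out <- character(n)
    for (g in seq_len(k)) {
      d <- spec$clusters[[g]]$sociodemo_dists[[f]]
      idx <- which(z == g)
      if (length(idx)) out[idx] <- sample(names(d), length(idx), replace = TRUE, prob = d)
    }
    out
  }), stringsAsFactors = FALSE)

  ages <- vapply(spec$clusters, function(cl) {
    if (is.null(cl$mean_age)) NA_real_ else cl$mean_age
  }, numeric(1))
  if (!anyNA(ages)) {
    sd_df$age <- round(pmax(0, stats::rnorm(n, mean = ages[z], sd = 12)), 1)
  }

  cohort <- cohort_matrix(
    person_id = sprintf("p%06d", seq_len(n)),
    conditions = cond, utilization = util, sociodemo = sd_df,
    catalog = catalog, util_schema = schema,
    enforce_multimorbidity = spec$enforce_multimorbidity
  )
  list(cohort = cohort, labels = z)
}
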