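# Small deterministic cohort: first two conditions always present (so the
# multimorbidity constraint holds), the rest Bernoulli; integer utilization.
make_small_cohort <- function(n = 20L, seed = 1L, extra_prev = 0.3) {
  set.seed(seed)
  catalog <- condition_catalog()
  cond <- matrix(stats::rbinom(n * 33L, 1L, extra_prev), n, 33L,
                 dimnames = list(NULL, catalog$name))
  cond[rowSums(cond) < 2, 1:2] <- 1
  util <- matrix(stats::rpois(n * 7L, 3), n, 7L,
                 dimnames = list(NULL, utilization_schema()))
  sd_df <- data.frame(
    age_band = sample(c("45_64", "65_84"), n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    family_type = sample(c("single", "married_couple"), n, TRUE),
    region = sample(c("capital", "zealand"), n, TRUE),
    employment = sample(c("employee", "retired"), n, TRUE),
    education = sample(c("short", "long"), n, TRUE),
    income_quartile = sample(paste0("q", 1:4), n, TRUE),
    stringsAsFactors = FALSE
  )
  cohort_matrix(person_id = sprintf("p%03d", seq_len(n)),
                conditions = cond, utilization = util, sociodemo = sd_df)
}

# Two well-separated Gaussian blobs in 2-D (plain matrix design).
make_blobs <- function(n_per = 100L, centers = rbind(c(0, 0), c(20, 20)),
                       sd = 0.5, seed = 1L) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(g) {
    matrix(stats::rnorm(n_per * 2L, sd = sd), n_per, 2L) +
      matrix(centers[g, ], n_per, 2L, byrow = TRUE)
  }))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# Borderline sensitivity fixture (generic 6 + 1 schema): two point groups
# separated in the condition block; two "bridge" persons share group A's
# conditions but sit at 65% of group B's utilization level, so they follow
# conditions at factors 0.5 and 1 and utilization at factor 2.
make_borderline_fixture <- function() {
  n_a <- 49L; n_b <- 49L
  cond <- rbind(
    matrix(rep(c(1, 1, 1, 0, 0, 0), n_a), ncol = 6L, byrow = TRUE),
    matrix(rep(c(0, 0, 0, 1, 1, 1), n_b), ncol = 6L, byrow = TRUE),
    matrix(rep(c(1, 1, 1, 0, 0, 0), 2L), ncol = 6L, byrow = TRUE)
  )
  util <- matrix(c(rep(0, n_a), rep(100, n_b), rep(65, 2L)), ncol = 1L)
  list(conditions = cond, utilization = util,
       groups = c(rep(1L, n_a), rep(2L, n_b), rep(1L, 2L)),
       bridge = c(rep(FALSE, n_a + n_b), TRUE, TRUE))
}
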