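test_that("O/E worked values and conversions behave as printed-table arithmetic", {
  expect_equal(round_half_up(oe_ratio(53.69, 20.55), 2), 2.61)
  expect_equal(round_half_up(pct_increase(7.41), 0), 641)
  expect_equal(oe_ratio(10, 10), 1)
  expect_equal(pct_increase(1), 0)
  expect_true(is.na(oe_ratio(5, 0)))
  # round_half_up differs from banker's rounding where it matters
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(0.5, 0), 1)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})

test_that("prevalence table satisfies its algebraic invariants", {
  cohort <- make_small_cohort(n = 40L, seed = 31L)
  set.seed(32)
  assign <- sample(1:3, 40L, replace = TRUE)
  tab <- prevalence_and_oe(cohort, assign)

  sizes <- table(assign)
  for (cn in c("depression", "copd")) {
    rows <- tab[tab$condition == cn, ]
    # pooled prevalence is the size-weighted average of cluster prevalences
    expect_equal(sum(rows$prevalence * as.integer(sizes)) / 40,
                 rows$overall_prevalence[1], tolerance = 1e-12)
    expect_equal(rows$oe, rows$prevalence / rows$overall_prevalence,
                 tolerance = 1e-12)
    expect_equal(rows$pct_increase, (rows$oe - 1) * 100, tolerance = 1e-12)
    expect_equal(rows$over_expected, rows$oe > 1)
  }
  expect_error(prevalence_and_oe(cohort, assign[-1]), "does not match")
})

test_that("conditions absent from the cohort get an undefined O/E sentinel", {
  cohort <- make_small_cohort(n = 10L, seed = 33L)
  cond <- cohort$conditions
  cond[, "parkinsons_disease"] <- 0
  cohort2 <- cohort_matrix(cohort$person_id, cond, cohort$utilization,
                           cohort$sociodemo)
  tab <- prevalence_and_oe(cohort2, rep(1:2, each = 5L))
  park <- tab[tab$condition == "parkinsons_disease", ]
  expect_true(all(is.na(park$oe)))
  expect_true(all(!park$over_expected))
})

make_portfolio_cohort <- function(sets) {
  catalog <- condition_catalog()
  cond <- matrix(0, length(sets), 33L, dimnames = list(NULL, catalog$name))
  for (i in seq_along(sets)) cond[i, sets[[i]]] <- 1
  util <- matrix(1, length(sets), 7L,
                 dimnames = list(NULL, utilization_schema()))
  sd_df <- data.frame(age_band = "45_64", sex = "female",
                      family_type = "single", region = "capital",
                      employment = "employee", education = "short",
                      income_quartile = "q1",
                      stringsAsFactors = FALSE)[rep(1, length(sets)), ]
  cohort_matrix(sprintf("p%02d", seq_along(sets)), cond, util, sd_df,
                enforce_multimorbidity = FALSE)
}

test_that("portfolios count exact condition sets only", {
  cohort <- make_portfolio_cohort(list(
    c("depression", "anxiety"),
    c("depression", "anxiety"),
    c("depression", "anxiety", "copd")
  ))
  tab <- portfolios(cohort, rep(1L, 3L), sizes = 2:3)
  two <- tab[tab$size == 2, ]
  three <- tab[tab$size == 3, ]
  expect_equal(two$conditions, "Anxiety + Depression")
  expect_equal(two$count, 2L)
  expect_equal(three$count, 1L)
  expect_true(grepl("COPD", three$conditions))
  # person with the 3-set does not count toward the 2-set
  expect_equal(sum(tab$count), 3L)
})

test_that("risk-factor exclusion recomputes cardinality before counting", {
  cohort <- make_portfolio_cohort(list(
    c("hypertension", "depression"),          # 1 left after exclusion
    c("hypertension", "depression", "copd"),  # 2 left
    c("depression", "copd")
  ))
  with_rf <- portfolios(cohort, rep(1L, 3L), sizes = 2:4,
                        include_risk_factors = TRUE)
  without_rf <- portfolios(cohort, rep(1L, 3L), sizes = 2:4,
                           include_risk_factors = FALSE)
  expect_equal(sum(with_rf$count), 3L)
  # persons 2 and 3 both reduce to {copd, depression}; person 1 vanishes
  expect_equal(sum(without_rf$count), 2L)
  expect_equal(without_rf$conditions[1], "COPD + Depression")
  expect_equal(without_rf$count[1], 2L)
})

test_that("portfolio rankings match brute-force dictionary counts", {
  set.seed(41)
  catalog <- condition_catalog()
  pool <- c("depression", "anxiety", "copd", "osteoarthritis", "epilepsy")
  sets <- replicate(30L, sample(pool, sample(2:4, 1L)), simplify = FALSE)
  cohort <- make_portfolio_cohort(sets)
  assign <- rep(1L, 30L)
  tab <- portfolios(cohort, assign, sizes = 2:4, top_n = 100L)
  label_sets <- lapply(sets, function(s) catalog$label[match(s, catalog$name)])
  for (m in 2:4) {
    oracle <- brute_portfolio_counts(label_sets, m)
    got <- tab[tab$size == m, ]
    expect_equal(sum(got$count), sum(oracle))
    expect_setequal(paste(got$conditions, got$count),
                    paste(names(oracle), oracle))
    if (nrow(got) > 1L) {
      expect_true(all(diff(got$count) <= 0))
      ties <- split(got$conditions, got$count)
      for (grp in ties) expect_equal(grp, sort(grp))
    }
  }
})

test_that("portfolio percentages use the cluster size as denominator", {
  cohort <- make_portfolio_cohort(list(
    c("depression", "anxiety"), c("depression", "anxiety"),
    c("depression", "copd"), c("copd", "anxiety", "epilepsy")
  ))
  tab <- portfolios(cohort, rep(1L, 4L), sizes = 2L)
  top <- tab[tab$rank == 1L, ]
  expect_equal(top$pct, 100 * 2 / 4)
})

test_that("sociodemographic percentages close to 100 and extremes are flagged", {
  cohort <- make_small_cohort(n = 40L, seed = 51L)
  # plant a known split: cluster 1 is 60/40 female/male, cluster 2 is 50/50
  sd_df <- cohort$sociodemo
  sd_df$sex <- c(rep(c("female", "male"), c(12L, 8L)),
                 rep(c("female", "male"), each = 10L))
  cohort2 <- cohort_matrix(cohort$person_id, cohort$conditions,
                           cohort$utilization, sd_df)
  assign <- rep(1:2, each = 20L)
  prof <- sociodemographic_profile(cohort2, assign)

  for (g in 1:2) {
    for (f in sociodemo_fields()) {
      expect_equal(sum(prof$pct[prof$cluster == g & prof$variable == f]), 100,
                   tolerance = 1e-8)
    }
  }
  fem <- prof[prof$variable == "sex" & prof$category == "female", ]
  expect_true(fem$is_highest[fem$cluster == 1])
  expect_true(fem$is_lowest[fem$cluster == 2])

  solo <- sociodemographic_profile(cohort2, rep(1L, 40L))
  expect_true(all(solo$is_lowest & solo$is_highest))
})

test_that("utilization means and condition-count bins are computed per cluster", {
  sets <- list(c("depression", "anxiety", "copd", "epilepsy"),
               condition_catalog()$name[1:12])
  cohort <- make_portfolio_cohort(sets)
  cohort$utilization[1L, "gp_visits"] <- 2
  uc <- utilization_and_counts(cohort, 1:2)
  gp1 <- uc$utilization_means[uc$utilization_means$cluster == 1 &
                                uc$utilization_means$variable == "gp_visits", ]
  expect_equal(gp1$mean, 2)
  expect_equal(uc$mean_conditions$mean, c(4, 12))
  big <- uc$condition_counts[uc$condition_counts$cluster == 2, ]
  expect_equal(big$pct[big$bin == ">=10"], 100)

  # pooled mean equals size-weighted average of cluster means
  pooled <- mean(rowSums(cohort$conditions))
  expect_equal(pooled, sum(uc$mean_conditions$mean * c(1, 1)) / 2)
})

test_that("cluster_profiles assembles a consistent bundle", {
  g <- generate_cohort(separated_preset(n = 300L, seed = 61L))
  prof <- cluster_profiles(g$cohort, g$labels)
  expect_equal(sum(prof$sizes$pct), 100, tolerance = 1e-8)
  expect_equal(sum(prof$sizes$n), 300L)
  expect_true(all(prof$condition_counts$pct >= 0))
  for (g_id in prof$sizes$cluster) {
    expect_equal(sum(prof$condition_counts$pct[prof$condition_counts$cluster == g_id]),
                 100, tolerance = 1e-8)
  }
  expect_s3_class(prof$portfolios_with_rf, "data.frame")
  expect_output(print(prof), "cluster_profiles")
})
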