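#!/usr/bin/env Rscript
# Stage 4 — characterize the clusters.
#
# Sociodemographics enter here for the first time: the clusters were formed
# on conditions + utilization only and are now described by size, raw
# utilization means, condition counts, sociodemographic distributions
# (lowest/highest flagged), prevalence with O/E ratios, and exact
# chronic-condition portfolios with and without the three risk factors.

library(morbiclust)

out_dir <- "results/analysis"
cohort <- read_cohort(file.path(out_dir, "cohort.csv"))
assign <- utils::read.csv(file.path(out_dir, "assignments.csv"))$cluster

prof <- cluster_profiles(cohort, assign)
utils::write.csv(prof$sizes, file.path(out_dir, "cluster_sizes.csv"),
                 row.names = FALSE)
utils::write.csv(prof$prevalence, file.path(out_dir, "prevalence_oe.csv"),
                 row.names = FALSE)
utils::write.csv(prof$utilization_means,
                 file.path(out_dir, "utilization_means.csv"), row.names = FALSE)
utils::write.csv(prof$condition_counts,
                 file.path(out_dir, "condition_counts.csv"), row.names = FALSE)
utils::write.csv(prof$sociodemo, file.path(out_dir, "sociodemo_profile.csv"),
                 row.names = FALSE)
utils::write.csv(prof$portfolios_with_rf,
                 file.path(out_dir, "portfolios_with_rf.csv"), row.names = FALSE)
utils::write.csv(prof$portfolios_without_rf,
                 file.path(out_dir, "portfolios_without_rf.csv"),
                 row.names = FALSE)

print(prof)
cat("\nmost common size-2 portfolios (risk factors included):\n")
top2 <- prof$portfolios_with_rf
top2 <- top2[top2$size == 2 & top2$rank == 1, ]
print(data.frame(cluster = top2$cluster, portfolio = top2$conditions,
                 count = top2$count, pct = round_half_up(top2$pct, 2)),
      row.names = FALSE)
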