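# morbiclust

Weighted k-means segmentation of multimorbidity cohorts.

## What it does

People with multimorbidity (two or more chronic conditions) differ not
only in *which* conditions they carry but in how heavily they use the
healthcare system. `morbiclust` clusters a person-level cohort jointly on
33 binary chronic-condition indicators and 7 yearly healthcare-utilization
counts, then describes the resulting clusters with sociodemographic
distributions, observed/expected (O/E) prevalence ratios and exact
chronic-condition portfolios. It is aimed at health-services researchers
working with registry extracts — and, because such microdata cannot be
shared, it ships a synthetic registry-cohort generator with planted
cluster structure so the whole pipeline is testable end to end.

The method:

1. **Standardize** all 40 clustering variables to zero mean, unit
   variance, then multiply the utilization block by the domain-balancing
   weight **w = √(33/7) ≈ 2.1712**, so both variable blocks contribute
   equally to expected squared Euclidean distances.
2. **Cluster** with Hartigan–Wong k-means under a stability protocol:
   each run keeps the best of 25 random starts; 200 runs record the
   minimum WCSS; if the minimum recurs in more than 10 runs it is
   accepted, otherwise 100 further runs are executed.
3. **Select k** by scanning k ∈ [2, 20] with the WCSS elbow, the
   Calinski–Harabasz index and a simplified (centroid-based) silhouette —
   reported as a guide, never auto-thresholded.
4. **Profile** clusters: sizes, raw utilization means, condition-count
   distributions, sociodemographics with lowest/highest flags, O/E ratios
   (cluster prevalence / population prevalence), and portfolios counting
   persons with *exactly* a given condition set, with and without the
   three risk factors (hypertension, high cholesterol, obesity).
5. **Stress-test** the weighting: re-cluster at 0.5w and 2w, match
   clusters optimally to the base solution, and report confusion matrices
   and diagonal agreement.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
simulated registry-like cohort (n = 10,000, seeded) whose four planted
clusters copy the published profile of the Danish multimorbid population:

```sh
Rscript analysis/01_simulate.R     # cohort.csv + true labels
Rscript analysis/02_select_k.R     # selection curve over k = 2..8
Rscript analysis/03_cluster.R      # stability protocol at k = 4
Rscript analysis/04_profile.R      # O/E, portfolios, sociodemographics
Rscript analysis/05_sensitivity.R  # re-cluster at 0.5w and 2w
```

Stage 1 prints the planted structure it drew:

```
simulated 10000 persons (seed 2026)
mean conditions per person: 3.58 (published cohort: 3.26)
planted cluster shares (%): 1.89 / 0.43 / 77.7 / 19.98
```

Stage 2 reproduces the characteristic model-selection picture on this
kind of data — WCSS falls smoothly with no clean elbow and both validity
indices peak at k = 2 while k = 4 remains acceptable, so the analysis
proceeds at k = 4 on interpretability grounds:

```
 k     wcss  ch_index silhouette
 2 597766.8 1039.7822  0.3843215
 3 558283.4  910.1126  0.3623198
 4 534063.8  785.2983  0.2405676
 ...
Calinski-Harabasz argmax: k = 2; silhouette argmax: k = 2
```

Stage 3 clusters at k = 4 and compares with the planted truth (90.7%
matched agreement at this desk scale — the two small planted clusters,
0.4% and 1.9% of the cohort, are genuinely hard at n = 10,000). Stage 5
then shows the weighting is robust for the recovered solution:

```
factor 0.5 x w: diagonal agreement 98.8%
factor 2.0 x w: diagonal agreement 99.7%
```

In code, the same pipeline is four calls:

```r
library(morbiclust)
sim    <- generate_cohort(registry_preset(n = 10000, seed = 2026))
design <- build_design(sim$cohort)             # standardize + weight
rep4   <- stability_protocol(design, k = 4, seed = 1)
prof   <- cluster_profiles(sim$cohort, rep4$best$assignments)
```

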