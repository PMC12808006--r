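---
title: "Domain-balanced weighted k-means for multimorbidity segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-balanced weighted k-means for multimorbidity segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbiclust)
```

## The problem

Multimorbidity — carrying two or more chronic conditions — concentrates
healthcare utilization in ways that condition lists alone do not reveal.
Segmenting a multimorbid population only by which conditions people have
lets the most prevalent conditions dominate, and treats utilization as an
afterthought. `morbiclust` implements the alternative: cluster persons
jointly on their 33 binary chronic-condition indicators *and* their 7
yearly healthcare-utilization counts (hospitalizations, bed days,
medication usage, outpatient visits, GP visits, specialist visits,
psychologist visits), with the two variable blocks balanced so that
neither dominates by mere dimensionality. Sociodemographic variables
(age band, sex, family type, region, employment, education, income
quartile) never enter the clustering; they are used afterwards to
describe the clusters.

## The model

### Standardization and the domain weight

All 40 clustering variables are standardized to zero mean and unit
variance — binary flags included, so that rare and common conditions
carry equal a-priori weight. We use the sample standard deviation
(divisor $n-1$); at registry scale the choice is numerically irrelevant,
but it must be fixed for exact reproducibility. A condition absent from
(or present in) everyone has zero variance and is rejected with an error
rather than silently dropped.

For two independent persons, each standardized coordinate difference has
expectation $E(z_1 - z_2)^2 = 2$, so the condition block contributes
$2 \times 33$ to the expected squared Euclidean distance and the
utilization block only $2 \times 7$. Multiplying the standardized
utilization columns by

$$ w = \sqrt{33/7} \approx 2.1712 $$

equalizes the two expected contributions. This derivation assumes
independence between columns; we implement the stated formula without
re-deriving it for correlated data. The weight enters once,
multiplicatively, before any distance computation, and all WCSS values
and validity indices are reported in this weighted space. A scalar
`weight_factor` on top of $w$ is the only tunable weighting — it exists
for the sensitivity analysis (factors 0.5 and 2), not as a modelling
dial.

We do not cap or winsorize the utilization counts before
standardization; heavy-tailed inpatient use therefore produces
standardized values far from zero, which is informative here (it is
exactly what distinguishes an inpatient-heavy cluster) but means single
extreme persons can pull centroids.

### Hartigan–Wong k-means

Clustering uses the Hartigan–Wong algorithm: after a Voronoi assignment
of the initial centroids, single points move between clusters whenever
the size-adjusted transfer gain

$$ \frac{n_t\, d^2(x, c_t)}{n_t + 1} \;<\; \frac{n_s\, d^2(x, c_s)}{n_s - 1} $$

holds for the best target $t$, so every accepted move strictly lowers
the total within-cluster sum of squares (WCSS). This typically reaches
lower WCSS than plain Lloyd iterations. Numerical choices:

* **Initialization.** $k$ distinct observations sampled uniformly
  without replacement. No k-means++ seeding — the protocol's brute
  multi-start scheme replaces it.
* **Ties.** A point equidistant from two centroids goes to the lower
  cluster index; results are deterministic given the centroids.
* **Empty clusters.** If the initial Voronoi partition leaves a cluster
  empty, it inherits the point farthest from its own centroid (taken
  from clusters that can spare one), guaranteeing all $k$ clusters are
  non-empty. Singletons never transfer out, so clusters cannot empty
  during iteration.
* **Transfer tolerance.** A move must improve WCSS by a relative
  $10^{-12}$ — strict descent in floating point, which rules out
  cycling; the iteration cap is `max_iter = 100` passes with a
  non-convergence flag.
* **Round-off.** Centroids are updated incrementally during passes and
  recomputed exactly (with the WCSS) at the end, so the returned
  centroids are within-cluster means to machine precision.

The core is compiled (Rcpp), as in every k-means implementation intended
for cohorts beyond toy size.

### The stability protocol

One *run* = 25 random initializations with the lowest-WCSS solution
kept. For each $k$, 200 runs are executed and each run's minimum WCSS
recorded. If the overall minimum recurs in more than 10 of the 200 runs,
that solution is accepted; otherwise 100 additional runs are executed
and the overall best kept. Two readings of this protocol were possible —
recurrence of the exact *partition* or of the WCSS *value*; we count
recurrences by value, within a relative tolerance of $10^{-10}$ (WCSS
values are compared as reals, and floating point requires a tolerance).
Both protocol levels are configurable; tests and the bundled analysis
scripts use desk-scale settings (typically 10–20 runs of 5 starts).
Reproducibility comes from a single master seed from which per-run
sub-seeds are drawn up front, so any individual run can be replayed in
isolation.

### Choosing the number of clusters

`selection_curve()` scans $k \in [2, 20]$ (any sub-range works) and
reports, per $k$: the protocol's minimum WCSS (elbow curve), the
Calinski–Harabasz index

$$ \mathrm{CH}(k) = \frac{\mathrm{BCSS}/(k-1)}{\mathrm{WCSS}/(n-k)}, $$

and the mean *simplified* silhouette, in which $a_i$ is the distance to
the own centroid and $b_i$ the minimum distance to any other centroid,
$s_i = (b_i - a_i)/\max(a_i, b_i)$ (defined 0 when $a_i = b_i = 0$).
The centroid form — rather than mean pairwise distances — is what makes
the silhouette linear in $n$ and thus usable at registry scale. Both
indices are computed in the weighted space, consistent with the WCSS;
mixing spaces would make the three criteria incomparable. Degenerate
cases: CH requires $1 < k < n$ and returns `Inf` when WCSS is exactly 0.

The package deliberately does **not** auto-pick $k$. On realistic
registry-like data the indices typically peak at $k = 2$ while the elbow
is ambiguous (the bundled `analysis/02_select_k.R` reproduces exactly
this behavior on simulated data); the choice of $k = 4$ in the published
analysis combined statistical criteria with model simplicity and
clinical interpretability, which is a judgment call. `suggest_k()`
reports each index's argmax as a convenience and nothing more.

## Cluster profiling

`cluster_profiles()` reproduces the descriptive tables:

* **Prevalence and O/E.** Per condition and cluster, the within-cluster
  prevalence and the observed/expected ratio (cluster prevalence over
  population prevalence). O/E is always computed from *unrounded*
  prevalences; printed-table reproduction uses round-half-up to the
  displayed digits. This order matters: recomputing O/E from rounded
  table cells can differ in the last digit (the bundled reference table
  shows such cases), and unrounded-first is the only self-consistent
  rule. Conditions with zero population prevalence get an `NA` sentinel.
  The percent increase is $(\mathrm{O/E} - 1) \times 100$.
* **Portfolios.** A chronic-condition portfolio of size $m$ counts
  persons with *exactly* that set of $m$ conditions and no others. In
  the risk-factor-excluded variant the three risk factors (hypertension,
  high cholesterol, obesity) are removed from every person's set before
  cardinality is determined — a person left with fewer than two
  conditions then contributes to no portfolio, which follows directly
  from the exactness rule. Rankings are by count descending with
  lexicographic tie-breaks (no rule was published; ties must break
  deterministically); percentages use the cluster size as denominator,
  which reproduces the published values.
* **Sociodemographics.** Percentage distributions per cluster with the
  lowest and highest cluster flagged per category row; a mean-age row
  appears when the cohort carries a numeric `age` column (the schema's
  age bands cannot yield a mean).
* **Utilization and condition counts.** Means of the *raw* counts (not
  the standardized, weighted values) per cluster, and the condition-count
  distribution binned $2..9$ and $\ge 10$.

## Weight sensitivity

`weight_sensitivity()` re-runs the full protocol with the utilization
weight at $0.5w$ and $2w$, matches each perturbed solution to the base
solution, and reports matched confusion matrices and the diagonal
agreement. Matching maximizes the diagonal by optimal assignment
(Hungarian-style, via weighted bipartite matching) on the $k \times k$
contingency table — the only rule consistent with reading agreement off
the diagonal; the matcher absorbs arbitrary relabelings, and solutions
with unequal label counts are padded with empty clusters. Perturbed runs
reuse the protocol parameters with fresh seeded substreams; whether the
published runs shared seeds is unknowable, and the analysis asserts
nothing about it. Agreement is reported as a fraction and as a
percentage to one decimal.

## The synthetic registry generator

Registry microdata cannot be shipped, so every downstream stage is
exercised on synthetic cohorts with planted structure. Per person: a
cluster from the mixing proportions; conditions as independent
Bernoulli draws at the cluster's prevalences; utilization as negative
binomial in the mean/dispersion parameterization
($\mathrm{Var} = \mu + \mu^2/\theta$, so smaller $\theta$ means heavier
tails) — registry utilization is overdispersed, and a cluster with mean
bed days near 30 next to one near 0.14 is not Poisson; sociodemographics
from per-cluster categorical distributions. Multimorbidity enforcement
redraws the *condition vector only* until it reaches two conditions,
preserving mixing proportions and utilization distributions exactly, and
errors (naming the offending clusters) if a rejection budget is
exhausted.

Two presets exist:

* `registry_preset()` plants the published four-cluster profile: exact
  cluster shares (2.03%, 0.43%, 77.59%, 19.96%), per-cluster condition
  prevalences and utilization means from the bundled reference tables,
  and the published sociodemographic distributions (renormalized to sum
  to one, absorbing table rounding). Dispersions are this package's
  choice, not a published quantity: 0.5 for the two inpatient variables
  (bed days, hospitalizations), 1.0 elsewhere.
* `separated_preset()` is the planted-recovery test bed: four clusters
  with disjoint signature-condition blocks at prevalence 0.95 against a
  0.02 background, distinct utilization profiles with near-Poisson noise
  (dispersion 100), and unequal mixing (0.10/0.15/0.45/0.30). It is
  calibrated so that the planted partition dominates at every weight
  factor in $[0.5, 2]$ — pairwise profiles differ by 0.93 on at least 16
  conditions, and both variable blocks vote for the same partition. That
  is the regime the recovery and sensitivity guarantees refer to.

What the generator does *not* emulate: within-cluster condition
correlations (only marginals are planted; real comorbidity is correlated
beyond cluster membership), longitudinal structure, and any dependence
between utilization and the specific conditions within a cluster.
Passing recovery tests on these cohorts therefore demonstrates that the
pipeline recovers planted mixture structure — not that four clusters are
the truth of any real registry.

## Problem sizes and runtime choices

The package's own test and analysis scale: planted-recovery and
selection-curve checks run at $n = 5{,}000$ with 10 runs of 5 starts
over $k \in [2, 8]$; the exhaustive-enumeration oracle (which certifies
the protocol reaches the global WCSS optimum) runs at $n \le 10$,
$k \in \{2, 3\}$, where all $k^n$ assignments can be enumerated; the
Monte-Carlo check of the balancing property uses $10^5$ simulated pairs;
the bundled analysis workflow simulates $n = 10{,}000$. The published
million-row, 200×25-start protocol is reached by changing arguments,
not code, and is deliberately out of desk scope.

## Known limitations

* Independent-Bernoulli conditions within clusters understate real
  comorbidity correlation; planted-recovery results are upper bounds on
  real-data performance.
* The domain-weight derivation assumes independent columns; with
  correlated blocks the "equal contribution" property is approximate.
* Hartigan–Wong scans points in order, so exact row-permutation
  equivariance holds only where the optimum is unambiguous.
* The simplified silhouette rewards centroid-tight clusters and can
  rank very unequal-sized solutions differently from the full
  silhouette.
* No statistical testing of between-cluster differences is provided
  (none was published), and clusters are not auto-labeled clinically.
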