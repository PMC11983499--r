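---
title: "Mining and clustering temporal multimorbidity trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and clustering temporal multimorbidity trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mltctraj` mines temporally ordered multimorbidity trajectories from dated
first-diagnosis records and clusters them through a shortest-path
condition-similarity network. This vignette is the package's account of the
method: the statistical model at each stage, the parameters that matter and
why their defaults are what they are, the numerical conventions adopted
where the method leaves room, and what the synthetic cohort generator does
— and does not — establish about behaviour on real data.

## Data model

The pipeline consumes a long-format table of diagnosis events (patient,
condition label, calendar date, source) and a demographics table (sex,
birth date, optional death date, deprivation quintile, ethnicity),
optionally supplemented by hospital stays (admission/discharge) and deaths
with an ICD-10 underlying cause. Events are reduced to a *first-diagnosis
table*: per (patient, condition) the earliest date over all sources, each
patient's rows forming their chronological sequence of first diagnoses.
Within a patient, same-day diagnoses are ordered by condition label so that
every downstream computation is deterministic under input reordering.

The analysis is stratified by sex and an age band split at 45 years (the
age around which chronic-condition prevalence rises sharply, and earlier
ageing-related onset is reported in intellectual-disability populations).
A patient's age is computed in completed years at a reference date. Which
reference date to use is genuinely open when a patient's records span
decades; the package defaults to the **end of individual follow-up**
(death or study end) because it is deterministic and uses only fields every
cohort has, with `first_ltc` and `midpoint` policies available. Age exactly
45 falls in the upper band ("45 and above"). Each patient belongs to
exactly one stratum; the four strata partition the cohort, a property the
test suite asserts.

## Stage 1: directed condition pairs

Within a stratum of N patients, a condition pair (C1, C2) is a *candidate*
when at least `min_shared = 10` patients carry both conditions with an
absolute separation of at least `min_gap_days = 183` days between the two
first diagnoses. Six months is encoded as 183 fixed days rather than
calendar-month arithmetic so results do not depend on locale or month
lengths. The two clauses are applied jointly — the gap clause expresses
temporality, so it qualifies the *shared patients*, while the association
test below uses all patients with both conditions:

* **Association.** Fisher's exact test (two-sided) on the 2×2 table
  both / C1-only / C2-only / neither. Two-sided is the conservative choice
  where sidedness is not dictated by the question; a one-sided variant
  remains available through the underlying test if needed. A table with a
  zero row or column margin carries no information and is flagged
  degenerate with p = 1. The odds ratio is reported as the sample
  cross-product ratio (infinite when an off-diagonal cell is zero).
* **Multiplicity.** Bonferroni over the candidate pairs of the stratum:
  adjusted p = min(1, m·p) with m the stratum's candidate count, keeping
  pairs with adjusted p < `alpha_pair = 0.001`. The correction family is
  the stratum because each stratum is analysed and reported independently.
  The threshold is read as applying to the *adjusted* p-value.
* **Direction.** An exact binomial test (success probability 1/2) on the
  order counts n_forward vs n_backward. Patients whose two diagnoses lie
  closer than the gap (including same-day) carry no directional
  information and are excluded from the binomial denominator — a flag on
  the counts makes the alternative reading auditable. If p <
  `alpha_direction = 0.05`, the direction is the more frequent order;
  otherwise the pair is undirected (↔). The reported mean ± SD interval is
  computed over *all* patients with both conditions, regardless of order,
  in years of 365.25 days.

Both exact tests are delegated to the standard R implementations; the test
suite verifies them against independent enumeration oracles (hypergeometric
point-probability sums over a grid of tables up to total 60; binomial tail
sums for all n ≤ 30) at 1e-12, and verifies the label-swap symmetry:
swapping C1/C2 flips the direction and changes nothing else.

## Stage 2: shared trajectories

Directed pairs are composed through shared middle conditions: C1 → C2 and
C2 → C3 yield the candidate C1 → C2 → C3 (C1 ≠ C3); an undirected pair
contributes both orders. The skip pair (C1, C3) is *not* required to be
significant — the composition rule is read literally — but
`require_all_pairs = TRUE` enables the stricter variant. A patient supports
a trajectory when their first-diagnosis dates respect the order with each
consecutive gap ≥ `min_gap_days`; intervening diagnoses of other conditions
are ignored (the trajectory is a subsequence of the patient's chronology).
Setting the gap to 0 disables the separation rule but still requires
strictly increasing dates.

Among trajectories over the same unordered condition set, only the most
frequent sequence is retained, ties resolved to the lexicographically
smallest sequence; trajectories with fewer than `min_traj_patients = 10`
supporters are dropped (the threshold is configurable since "more than ten"
and "a minimum of ten" are both defensible readings; ≥ 10 is used).
Three-condition trajectories feed clustering; the composition machinery
itself is length-agnostic.

## Stage 3: the condition network and trajectory similarity

Every retained trajectory contributes its *consecutive* condition pairs as
undirected edges (C1→C2→C3 gives C1–C2 and C2–C3, mirroring the drawn
chains of a trajectory diagram; an `all_pairs` mode adds the skip edge).
The edge frequency f(e) counts trajectories containing the adjacency, each
trajectory once; `frequency_mode = "patients"` weighs by supporting-patient
counts instead for analyses where trajectory support sizes differ wildly.
Edge weight is w(e) = 1/f(e): frequently co-traversed pairs lie closer.

Condition similarity is sim(ci, cj) = 1 / shortest_path(ci, cj) with
Dijkstra shortest paths (via `igraph`), and trajectory similarity is the
mean over all 3 × 3 condition pairs (the matrix is symmetric and
non-negative by construction). Three conventions deserve note:

* **Unreachable pairs** get similarity 0, the limit of the reciprocal as
  path length grows.
* **Self-similarity** is undefined by the reciprocal transform (zero path
  length). The diagonal terms of the trajectory-similarity formula need a
  value, so sim(c, c) := 1/w_min — the maximum attainable inter-node
  similarity, keeping the diagonal on the same scale without infinities. A
  `"zero"` mode exists for analyses that prefer to exclude the diagonal
  contribution.
* **Range.** The reciprocal transform only maps into (0, 1] when all edge
  weights are ≥ 1, i.e. when every f(e) = 1. With repeated adjacencies
  (f > 1) similarities exceed 1; the package keeps the literal formula and
  documents this, and `normalise = TRUE` rescales frequencies by their
  maximum so the smallest weight is 1 and the (0, 1] range holds.

The Dijkstra lengths are verified against two independent oracles
(a hand-written Floyd–Warshall and exhaustive simple-path enumeration) on
1,000 random graphs of up to 8 nodes, and the similarity matrix is checked
for symmetry, non-negativity, permutation equivariance, and monotonicity —
adding a trajectory can only add edges or raise frequencies, so no
similarity may decrease.

## Stage 4: spectral clustering and choosing k

The similarity matrix is treated as a graph affinity. The spectral
embedding takes the k leading eigenvectors of the degree-normalised
affinity D^(-1/2) A D^(-1/2) (equivalently the k smallest of the symmetric
normalised Laplacian), row-normalises them, and k-means clusters the
embedded points — 10 restarts, `iter.max` 100, all randomness driven by a
fixed seed (default 42) so identical inputs give identical labels.
Explicit settings are pinned rather than inheriting any library's
version-dependent defaults.

The number of clusters is chosen by the **Calinski–Harabasz score**
(between/within dispersion scaled by (n−k)/(k−1)), computed on the
spectral-embedding coordinates the k-means step actually used — the score
needs a feature space, and this keeps it consistent with the clustering
geometry. Candidates run from `k_min = 2` to `k_max = 10` (capped at
n − 1).

CH is undefined at k = 1, yet sparse strata genuinely can carry a single
cluster or none. The package therefore applies an explicit
**degenerate-structure rule**: the arg-max-CH solution is rejected in
favour of a single cluster when its smallest cluster has fewer than
`min_cluster_size = 3` members or its mean silhouette width — computed on
the dissimilarity 1/(1 + sim) — falls below `min_silhouette = 0.05`. Both
thresholds are configurable and logged in the cluster report. The
silhouette default was calibrated on the two regimes the rule must
separate: on near-uniform random affinities (no structure) the mean
silhouette of the best CH solution sits around 0.01 or below, while on
planted-block matrices with genuine communities it sits at 0.15 and above;
0.05 splits the two bands with a wide margin on either side. (An
embedding-coordinate silhouette was evaluated for this rule and rejected:
k-means always finds *some* split of the embedded points, so that variant
cannot distinguish noise from structure.) Strata with fewer than
`k_min + 1` trajectories skip clustering entirely with a logged notice.

## Cluster characterisation

Each cluster is summarised the way multimorbidity cluster tables are
usually presented: the body-system composition counts each condition slot
of each trajectory once (3 slots per trajectory, percentages summing to
100); patient counts are unique patients over the cluster's trajectory
supports; mortality percent is deaths among cluster patients over the study
period; the mortality rate accrues person-years from each patient's first
LTC diagnosis (configurable to study start) to death or study end, reported
per 100 person-years; long hospital stays are stays strictly longer than 4
days (the strict reading matches the footnote convention that defines such
published values; the threshold is configurable); causes of death are
ICD-10 underlying causes bucketed by a shipped chapter code-range table,
reporting the top five chapters among the deceased, ties broken
alphabetically, unmappable codes bucketed as "other".

## The synthetic cohort generator

Real linked EHR cohorts of this kind are access-restricted, so the
generator is a first-class, tested module that emulates the *structure* of
such data with known ground truth:

* **Onsets.** Per patient and condition, an exponential waiting time at
  the condition's annual baseline hazard. Defaults span 0.010–0.024 per
  year across 20 conditions drawn from the shipped 40-condition
  vocabulary, giving roughly 20–40% lifetime prevalence over the 22-year
  window (2000–2021) — the prevalence range typical of leading long-term
  conditions in high-multimorbidity cohorts.
* **Planted directed pairs.** After a trigger condition's onset, the
  target condition's hazard multiplies by `lift` from the trigger onset
  plus an exponential lag (mean `mean_lag_days`), sampled by inverting the
  piecewise cumulative hazard. This single mechanism yields both the
  association signal (Fisher) and the directionality signal (binomial).
* **Planted communities.** Conditions are partitioned into communities
  (default two: cardio-metabolic/renal and neuro-psychiatric/digestive,
  echoing the cluster types reported for such cohorts); each patient draws
  a mean-1 gamma frailty per community (variance 1 by default) multiplying
  that community's hazards. This creates within-community co-occurrence,
  hence within-community pairs, trajectories and graph communities — the
  ground truth for cluster-recovery tests, where each trajectory's
  expected label is its majority community.
* **Demographics and outcomes.** Sex ratio 52.3 : 47.7 male : female and
  ages uniform 18–80 at study start, echoing the published descriptive
  table of the motivating cohort type; deaths from an exponential hazard
  (1.5%/year default) truncate subsequent onsets; hospital stays arrive at
  0.25/year with log-normal durations (median 3 days) so a realistic
  minority of stays exceed the 4-day long-stay threshold; causes of death
  are sampled from a fixed ICD-10 code pool weighted towards circulatory,
  respiratory and neoplastic causes.

Everything is reproducible from a single seed, and the generated tables
round-trip through the package's CSV readers.

One modelling point matters for calibration experiments: **shared death
truncation induces genuine positive dependence** between conditions (two
conditions are both absent when the patient dies early), which Fisher's
test correctly detects. The independence (null) configuration used for
family-wise-error measurement therefore disables mortality
(`death_rate = 0`) along with lifts and frailty; with mortality on, an
elevated pair-selection rate on "independent" cohorts is real association,
not a defect of the testing machinery.

**What passing tests do and do not show.** The generator produces clean
exponential-hazard onsets, exact first-diagnosis dates, a closed
vocabulary, and independence between the diagnosis process and data
quality. Real EHRs have coding noise and under-diagnosis, registration
gaps, age- and period-varying hazards, and deprivation-correlated risk
(a hook exists but is not modelled). Recovery of planted structure
therefore demonstrates the pipeline's correctness and statistical power
under its stated assumptions — not that any particular clinical cohort
will yield equally clean clusters.

## Problem sizes and verification

The test suite runs every stage against oracles and planted ground truth
at sizes chosen to make the statistical checks sharp while keeping the
suite quick: exact-test sweeps complete up to table total 22 plus 4,000
random tables to total 60; 1,000 random graphs for the shortest-path
oracles; 200 independent null cohorts of n = 2000 for family-wise error;
20 seeds at lift 10 for directed-pair recovery; 10 end-to-end seeds of
n = 2000 for community recovery (adjusted Rand index); byte-identity runs
for determinism. `scripts/acceptance.R` re-runs the same measurements from
scratch against the installed package and writes them as JSON.

## Known limitations

* The pipeline is frequentist screening plus unsupervised structure
  discovery; it does not adjust for covariates, model hazards (no
  relative-risk or DTW-style trajectory methods), or provide inference on
  the clusters themselves.
* Bonferroni within stratum is conservative for large vocabularies; the
  candidate-family definition is the analysis unit, so cross-stratum
  multiplicity is intentionally not corrected.
* The inverse-frequency similarity exceeds 1 whenever adjacencies repeat;
  comparisons of similarity *levels* across graphs should use the
  normalised mode.
* Single-cluster verdicts come from an explicit calibrated rule, not from
  the Calinski-Harabasz score, which cannot express k = 1; the rule's
  thresholds are logged so any verdict can be audited.
* The 40-condition vocabulary mapping shipped with the package is a
  curated approximation for examples and synthetic data; real analyses
  should supply their own condition list and system/mental-health mapping.
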