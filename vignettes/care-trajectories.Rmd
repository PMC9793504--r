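---
title: "Deriving typologies of healthcare utilization trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving typologies of healthcare utilization trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caretraj)
```

## The analytical problem

Older adults use health services along several channels at once — visits
to physicians, emergency consultations, overnight hospital stays,
professional home care, nursing home residence — and the *joint,
longitudinal* pattern of that use is more informative than any single
year or channel. `caretraj` treats each person's follow-up as five
parallel categorical sequences (one annual state per channel over 11
waves) and derives a typology in three stages:

1. a **multichannel Optimal Matching (OM) dissimilarity** between every
   pair of individuals, with explicit states for death, incapacity and
   random nonresponse;
2. **clustering on the dissimilarity matrix** (complete linkage by
   default, Ward and PAM as alternatives), with the number of groups
   chosen by an average-silhouette and minimum-cluster-size criterion;
3. **cluster characterization**: bivariate screens (chi-squared tests,
   ANOVA for age) followed by a multinomial logistic regression with
   backward stepwise AIC selection, reporting odds ratios of cluster
   membership relative to the largest cluster.

Because cohort microdata of this kind are typically only available on
request, the package ships a seeded synthetic cohort generator whose
latent structure mirrors a published six-group typology, so the whole
pipeline is exercisable and testable end to end.

## States, sequences and the inclusion filter

Each channel has an ordinal alphabet with position 0 meaning *no
utilization* (`default_channel_specs()`): ambulatory care has four
levels (none/low/medium/high), the other channels three. Three overlay
states apply to all channels of a person-wave simultaneously:

* `DEAD` — absorbing: once dead, always dead;
* `INCAP` — too unwell to participate;
* `NR` — random nonresponse.

The study-inclusion rule keeps individuals with at least six *known*
waves, where a wave is known when it carries a channel level, `INCAP`
or `DEAD` (`filter_min_observations()`). Counting confirmed deaths as
observations is deliberate: an early-death trajectory is complete
information about the person's utilization history, not attrition, and
excluding those individuals would delete exactly the early-mortality
group from the typology.

## The cost model

For a channel with `K` ordinal levels the substitution cost between
states `a` and `b` is

```
s(a, b) = 2 * |pos(a) - pos(b)| / K
```

with the extended positions: levels at `0..K-1`, `INCAP` sharing
position `K-1` (incapacity is treated as equivalent to the highest
utilization level) and `DEAD` at position `K` (death is the furthest
state from no utilization). The maximum substitution cost is therefore
2 on every channel, and the indel cost is half of that — 1 — which
balances the weight given to the *timing* of states (substitutions)
against their *sequencing* (shifts). `NR` costs exactly the indel cost
against every other state: "equidistant to all other states" pins only
the equality, and the indel cost is the unique equidistant value that
keeps the matrix metric against the `DEAD`–`none` pair. With every
channel normalized to the same maximum and the same indel cost, equal
channel weights (the default) already prevent any single dimension
from dominating the pooled distance; weights remain configurable.

The multichannel distance runs a *single* dynamic programme on the
vector-valued states, adding the per-channel substitution costs at each
aligned time point (local interdependence) and using the summed indel
cost. With one channel it reduces exactly to ordinary OM. The
implementation pools the distinct multichannel person-wave profiles and
runs the edit-distance recursion in C++; the full matrix for ~2,300
individuals takes on the order of ten seconds on one core.

The default cost model is a metric, so the OM distance satisfies the
triangle inequality — this is checked exhaustively on sampled triples
in the test suite.

## Clustering and choosing the number of groups

`agglomerate()` builds the merge tree on the precomputed matrix
(`stats::hclust`); `cut_clusters()` renumbers labels by decreasing
size, so cluster 1 is always the largest group and serves as the
reference downstream. `pam_clusters()` offers partitioning around
medoids on the same matrix, and `silhouette_width()` computes
silhouettes directly from the dissimilarities (singleton clusters
contribute width 0, the common convention).

`select_solution()` operationalizes a two-part criterion:

* **size rule** — every cluster must hold at least `round(0.011 * n)`
  individuals (about 1% of participants; 25 when n = 2271). Groups
  smaller than that cannot be characterized meaningfully.
* **silhouette rule** — increasing `k` must not *distinctly* decrease
  the average silhouette width (ASW). A candidate `k` is vetoed when
  its ASW falls more than 0.05 below the best ASW among candidate
  partitions with `k' >= 3` up to it. Empirically this is a sharp
  signal: a split that halves a coherent group (for example, separating
  individuals by the position of a single missed questionnaire)
  collapses the ASW by 0.1–0.4, while genuine structure leaves it flat.
  The 2-cluster solution is excluded from the reference because
  splitting off the single most distant group always produces an
  inflated silhouette that says nothing about finer structure.

The largest `k` passing both rules is selected and the full ASW-vs-k
curve is attached to the solution, so the choice can be audited or
overridden (`run_pipeline(k = ...)`).

## Cluster characterization

`prepare_covariates()` applies the missing-data policy: a categorical
covariate whose missing share exceeds 0.5% gains an explicit
`"missing"` category; rarer missingness drops the affected individuals
from the model sample. `bivariate_tests()` screens every covariate
(Pearson chi-squared without continuity correction — the tables are
`k x c`, where the correction does not apply — and one-way ANOVA for
age). Covariates significant at the 5% level enter a multinomial
logistic regression of cluster membership with the largest cluster as
the reference outcome.

`fit_multinomial()` maximizes the likelihood by full Newton–Raphson
with step halving, declaring convergence when the log-likelihood
improves by less than 1e-8 (at most 200 iterations); standard errors
come from the observed information matrix and odds ratios are
`exp(beta)` with Wald 95% intervals. Quasi-complete separation — a
covariate category with zero individuals in some cluster — is detected
from the category-by-cluster crosstabs and the affected odds ratios are
flagged non-estimable rather than reported as diverged numbers; this is
exactly the situation that arises when no member of a high-utilization
cluster has zero chronic conditions. Dummy coding uses the first
observed category as reference, age enters linearly, and
`backward_stepwise_aic()` removes whole covariates (all dummies at
once) one at a time while the AIC improves.

## What the synthetic cohort emulates

`simulate_cohort()` draws each of 3,053 individuals into one of six
latent archetypes and simulates the five channels wave by wave. All
numeric defaults live in one editable YAML file
(`system.file("extdata", "archetypes.yaml", package = "caretraj")`).

* **Channel dynamics.** Per archetype, channel and phase (waves 1–4,
  5–8, 9–11) a target distribution over levels plus a stickiness `rho`
  define the Markov kernel `rho * I + (1 - rho) * 1 t(target)`. The
  kernels were designed to the qualitative shapes of the six published
  trajectory groups: constant low utilization; escalation of formal
  home care from mid follow-up; low utilization with death or
  incapacity in the last three waves; high early ambulatory care and
  hospitalizations ending in permanent nursing-home residence; an early
  fatal event; constant top-level ambulatory and emergency care with
  low home care.
* **Overlays.** Death and incapacity are per-wave hazards (length 11);
  death is absorbing and recorded only while the individual is under
  follow-up. Permanent dropout — withdrawal from the study — turns all
  later waves into nonresponse, *including* a death occurring after
  withdrawal: without follow-up the death is simply not observed, and
  such individuals fail the inclusion filter. Transient nonresponse is
  at most one missed questionnaire per individual; repeat nonresponse
  is what the dropout process models. This split matters: unbounded
  per-wave random nonresponse concentrates several missed waves on a
  few individuals, and under the OM cost model those individuals form
  spurious "high-missingness" groups that a published utilization
  typology does not contain.
* **Calibration.** The dropout hazard is concentrated in waves 2–6 and
  calibrated so about 74.4% of simulated individuals pass the filter
  (2271 of 3053 in the study the typology comes from); the nonresponse
  probability is calibrated so nonresponse makes up about 5.9% of
  retained person-wave observations. Archetype prevalences in the
  configuration are *recruitment* values: because early deaths always
  pass the filter while other archetypes face attrition, the
  recruitment mix is proportional to the published (post-filter) shares
  divided by each archetype's retention rate, so the analyzed
  composition matches the published 83.3 / 4.9 / 4.4 / 1.5 / 3.8 /
  2.1%.
* **Covariates.** Baseline covariates are drawn independently per
  individual from archetype-conditional category probabilities (sex,
  living alone, self-perceived health, grip strength, chronic illness
  count, functional dependency), with "missing" as an explicit draw so
  the covariate-coding rules are exercised; age is uniform on 65–70
  shifted to each archetype's mean.

What the generator does **not** emulate: correlations between
covariates beyond their shared archetype, within-person correlation
between channels beyond the archetype profile, secular trends, and any
real-world ambiguity in the latent group structure — the archetypes are
well separated by construction, so a near-perfect recovery on synthetic
data shows the pipeline works, not that real cohorts cluster this
cleanly.

## Numerical and design choices

* Problem sizes: the packaged checks simulate the full 3,053-individual
  cohort; the pairwise distance stage pools distinct multichannel
  profiles and runs in C++, so a complete pipeline run takes well under
  a minute on one core. Property-style tests use smaller cohorts
  (40–800 individuals) and exhaustive enumeration on short sequences.
* The OM dynamic programme supports unequal sequence lengths, although
  cohort sequences always have 11 waves here.
* Agglomeration delegates to `stats::hclust`; merge-order ties are
  resolved by its deterministic implementation. Ward linkage on a
  non-Euclidean OM matrix (`ward.D2`) is a heuristic and is documented
  as such.
* `k = n` in PAM (every point its own medoid) is handled as an explicit
  degenerate case.
* The Newton optimizer adds a tiny ridge (1e-8) to the Hessian only if
  it is numerically singular, and uses a log-sum-exp safe softmax.
* Determinism: `simulate_cohort()` is bit-reproducible given its seed;
  every downstream stage is deterministic given its inputs.

## Known limitations

* The count-to-category cutoffs behind the channel alphabets are survey
  design choices; the default alphabets encode the published state
  labels, not any particular count thresholds.
* Only OM is implemented as the sequence dissimilarity; Hamming-type or
  spell-based alternatives are out of scope.
* The silhouette-drop threshold (0.05) and the 1% size fraction are
  conventions; both are arguments of `select_solution()` and should be
  stress-tested on real data.
* Odds ratios from the multinomial model assume the cluster labels are
  fixed; uncertainty from the clustering stage is not propagated.
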