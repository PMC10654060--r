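---
title: "Methods and design notes for the four-type VM analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the four-type VM analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vm4)
```

# The model

`vm4` operationalizes a two-axis typology of the vaginal microbiome (VM):
health status (healthy vs. bacterial vaginosis) is taken from clinical
metadata, and community structure (complex vs. simple) is derived from the
data. Crossing the axes yields four types — HC, HS, BVC, BVS — that are
treated as habitat classes for all downstream tests. The package's job is
threefold: derive the structure axis, test whether the four types are
statistically distinct at community and species level, and check whether
samples can be re-assigned to their types by supervised learning.

## The 10 typing metrics

Each sample is summarized by ten numbers:

* **Hill numbers** at q = 0, 1, 2, computed on relative abundances.
  `qD = (sum p_i^q)^(1/(1-q))` is the effective species count; q = 0 is
  richness, q = 1 the exponential of Shannon entropy (taken as the limit,
  since the formula is singular there), q = 2 the inverse Simpson
  concentration. `qD` is non-increasing in q; uniform communities give
  `qD = S` at every order.
* **Community dominance** `D_c` from Lloyd-style mean crowding:
  with per-species mean abundance `m_c` and variance `sigma_c^2`,
  `m_c* = m_c + sigma_c^2/m_c - 1` and `D_c = m_c*/m_c`. Dominance is
  computed on raw read counts, not relative abundances, and only over the
  species present in the sample.
* **Species dominance** `D_s = D_c - m_c*/m_s` of the three most dominant
  species. `D_s` is strictly increasing in the focal abundance `m_s`, so
  the top-3 by `D_s` coincide with the top-3 by abundance; ties break
  lexicographically by taxon identifier so results are deterministic.
* **Top-3 relative abundances.**

Two numerical conventions deserve note. First, the variance in the mean
crowding formula defaults to the sample (n − 1) convention, which is the
common choice in mean-crowding practice; `var_method = "population"`
switches to the divide-by-N convention, under which `D_c` is an exact
linear function of Simpson's concentration,
`D_c = N * sum(p_i^2) - N/T`. The test suite asserts that identity to
1e-9 under the population convention; under the sample convention it holds
only asymptotically. Second, samples with fewer than three taxa have their
missing top-k slots padded with zeros rather than dropped, so the feature
matrix is always complete.

## Dichotomization

Within each health group, K-means (Hartigan–Wong, k = 2, 10 restarts,
seeded) is run on the z-standardized 10-metric matrix. Standardization
matters: dominance and diversity live on scales two orders of magnitude
apart, and unstandardized Euclidean distances would be dominated by a
single column. k is fixed at 2 by the hypothesis design; no model
selection is attempted. The cluster with the higher mean Hill q = 1 is
labeled *complex*; an exact tie breaks toward the lower mean `D_c`.
Degenerate inputs (all samples identical) collapse to a single cluster
with a warning rather than an arbitrary split.

# Community-level tests

**Shared species.** The statistic is the number of taxa with positive
total count in both groups. Two nulls are provided: shuffling group labels
over samples, and redistributing each taxon's pooled reads over all
samples with probabilities proportional to sample depths. For the
shared-species count the read-redistribution null marginalizes exactly to
a binomial split of each taxon's pool between the two groups, which is
what the implementation draws. Composition is flagged as changed when the
observed count falls below the null expectation with one-sided P <= 0.05.

**Sloan near-neutral fit.** Under the neutral sampling model a taxon with
regional relative abundance p has local relative abundance
Beta(Nm·p, Nm·(1 − p)). The composite parameter Nm is estimated by
nonlinear least squares on occurrence frequency vs. mean relative
abundance. Two detection models are offered: the default integrates the
sampling process exactly (beta-binomial probability of at least one read
at the mean depth), while `detection = "threshold"` uses the common
approximation P(abundance > 1/depth). The default was chosen because the
threshold form systematically understates the detection of rare taxa and
biases Nm upward by 10–20% in parameter-recovery simulations at the
package's test scale. Species are classified above/below/neutral against
exact binomial 95% quantile bands around the fitted prediction; the bands'
nominal per-species coverage is slightly above 95%, but plug-in estimation
of the regional abundances (conditioning on detection) costs a few points
of coverage for rare taxa, so fully neutral simulations typically return a
neutral fraction around 0.9–0.95 rather than 0.95 exactly.

**Normalized stochasticity ratio (NSR).** For each sample pair the
observed similarity (Jaccard on presence/absence by default, Bray–Curtis
optional) is compared with its expectation under a null that redraws each
sample's taxa from the regional pool, preserving richness, with
probabilities proportional to regional abundance. For Bray–Curtis the
sample's positive counts are reassigned to the drawn taxa in
regional-abundance rank order; a uniformly random assignment would destroy
the rank-abundance coupling that every real community shares and would
read as determinism even for i.i.d. samples. Pairs more similar than
expected contribute `C_exp/C_obs`, pairs less similar contribute
`(1-C_exp)/(1-C_obs)`; both ratios are 1 under pure stochasticity, and the
mean ratio tends to 1/2 (not 0) under extreme determinism, so the
reported NSR is `2 * mean(ratio) - 1` clamped to [0, 1].

**Taylor's power-law extensions.** `V = a·m^b` is fit by OLS on the
log10–log10 scale. Type I treats each sample as a point (mean and
variance of abundances across the species present in it); type III treats
each taxon as a point (mean and variance across samples). The type III
point definition is an interpretation — "mixed-species spatial
heterogeneity" admits more than one reading — and is flagged as such.
Points with zero mean or variance are excluded as undefined on the log
scale; fits require at least 3 usable points. Parameter differences
between groups are tested by shuffling sample membership and refitting,
with two-sided P on |Δa| and |Δb|.

# Species-level specificity

Specificity of species i for type h is `Delta_ih = A_ih * B_ih`:
prevalence times the type's share of the species' mean relative abundance.
The mean abundance divides by all of the type's samples (zeros included),
which is what makes the extreme-generalist anchor `Delta = 1/H` exact.
Specificity diversity applies the Hill-number form to relative
specificities `lambda_i = Delta_ih / sum Delta_ih`.

The SP test works within a pair of types (H = 2): the per-species
statistic is the specificity difference `Delta_1 - Delta_2`, the null
remixes the pooled samples into groups of the original sizes and
recomputes, and P-values are BH-adjusted across species. The difference
(rather than the fold change) is the statistic because it remains
well-defined when one side is zero; the fold change is still reported for
volcano plots, with infinite values capped at a sentinel one decade beyond
the largest finite magnitude. *Unique* (US) status additionally requires
structural absence — prevalence exactly zero in the other type — not mere
significance; significant species present on both sides are *enriched*
(ES) on their higher-specificity side. All permutation P-values use the
add-one rule `(r + 1)/(n + 1)` and therefore never reach zero.

The SDP test compares the specificity diversity of two species categories
at each order in a q grid (default 0–4) by shuffling species, with their
specificities, between the categories. At q = 0 this reduces to a
richness comparison.

# The machine-learning harness

Six classifier families are wrapped behind one interface: multinomial
logistic regression (`nnet::multinom`), KNN with 17 neighbors
(`class::knn`), random forest (`randomForest`), gradient-boosted trees
(`xgboost`), an RBF-kernel SVM at cost 1 (`e1071::svm`), and a dense
neural network implemented in the package: two ReLU hidden layers (64/32
by default — the widths are not pinned down by the harness design and are
recorded as configurable), softmax output, momentum SGD starting at
learning rate 0.01, with the rate cut tenfold whenever 30 consecutive
epochs fail to improve the training loss and training stopped after the
third stall. "Precision" is held-out overall accuracy — the fraction of
test samples assigned their original type. Splits are stratified random
75/25; stratification (rather than simple random splitting) avoids
empty-class folds at the cohort sizes the package targets, and class
imbalance is otherwise left alone. Each repeat r re-seeds with
`seed + r`, so the full split sequence is reproducible, and deterministic
learners give bit-identical precision sequences across runs. External
evaluation never refits; OTU-view features are aligned by taxon name with
zero fill for taxa unseen at training.

# The synthetic cohort generator

The generator exists so that every pipeline stage has inputs with known
truth. It emulates the structural signature of the four types:

* **Top-3 share means** per type: HC (0.354, 0.229, 0.120),
  HS (0.646, 0.286, 0.036), BVC (0.378, 0.209, 0.119),
  BVS (0.783, 0.136, 0.034) — simple types near-monocultures with a
  collapsed runner-up, complex types flat.
* **Richness means** 29/13/30/14 (HC/HS/BVC/BVS), drawn per sample with
  SD 1.
* **Planted species**: each type owns its top-3 dominant taxa, 5 unique
  species (draw weight zero outside their type) and 10 enriched species
  (draw weight elevated 8× inside their type); the planted sets are
  disjoint by construction. Planted species sit at the 90th percentile of
  the core background weights, which puts their own-type prevalence near 1
  (complex) or around 0.4 (simple) while foreign types still pick enriched
  species up occasionally — the regime in which the SP test's US/ES
  distinction is exercised rather than trivialized.
* **Counts**: per-sample profiles are drawn from Dirichlet distributions
  (top shares at concentration 2000, background at 50) and converted to
  reads by multinomial sampling at a lognormal depth (median 30,000 reads,
  sdlog 0.5), giving the over-dispersion typical of 16S count data.
* **Dominance–depth coupling**: the dominant share is tilted by
  ±0.18 × log(depth/median) — positive for simple types, negative for
  complex. Because the per-sample variance of abundances scales with the
  squared dominant share, this induces type-I Taylor exponents above 2 in
  simple groups and below 2 in complex groups, the heterogeneity ordering
  the typology predicts.

Two dispersion choices are deliberately tighter than real cohorts: the
top-share concentration (2000; SD of the dominant share about 0.01–0.02)
and the richness SD (1). They were set so that the four types are
statistically distinguishable at the level the package documents —
in particular HC vs. BVC, whose mean profiles differ only slightly —
while every distributional *target* (the means above) stays at its
published magnitude. Real 16S cohorts carry substantially more
within-type spread, along with batch effects, primer biases, and
study-level structure that the generator does not attempt to emulate.
Passing tests on synthetic cohorts therefore demonstrate correctness of
the machinery and recoverability of planted structure, not expected
performance on clinical data.

`generate_neutral_metacommunity()` draws local communities from
Dirichlet(Nm·p) followed by multinomial sampling, whose marginals are
exactly the Beta(Nm·p, Nm·(1−p)) the Sloan fit assumes, so Nm is
recoverable by construction. The regional pool spans about 2.5 decades of
abundance; a much longer rare tail degrades the plug-in estimate of
regional abundances (rare taxa are only observed conditional on
detection) and with it the neutral-fraction calibration.

# Problem sizes and runtime choices

The shipped tests and the acceptance script run at deliberately modest
sizes: cohorts of 4 × 250 samples over a 200-taxon pool, 199–999
permutations per test, 60–100 null simulations for the NSR, and 10
split repeats for the ML harness. These sizes keep the full suite under
half a minute on one CPU while leaving every statistical conclusion
qualitatively stable across seeds; all of them are arguments, not
constants, so larger studies can scale them up.

# Known limitations

* The structure axis is derived per cohort; the package does not model
  transitions between types over time.
* The SP test permutes whole samples, so its null preserves within-sample
  composition but not study-level batch structure.
* The NSR normalization maps the mean similarity ratio linearly onto
  [0, 1]; alternative published normalizations differ in how they treat
  the deterministic limit, and values near the middle of the scale should
  be compared only within one choice of normalization.
* Fisher's exact test on neutral-model class counts treats species as
  independent, which compositional data only approximate.
* The dense network is a minimal reference implementation; it is adequate
  for the desk-scale feature tables the package targets, not a substitute
  for a tuned deep-learning stack on large OTU matrices.
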