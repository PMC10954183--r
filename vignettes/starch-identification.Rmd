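---
title: "Discriminant identification of starch grains: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant identification of starch grains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starchid)
```

## The problem

Starch granules preserved on stone tools carry diagnostic morphology: size,
outline shape, the position of the hilum (the granule's growth center), the
presence and shape of hilum fissures, pressure facets, and the style of the
extinction cross seen under crossed polarizers. Species identification from
these traits is hard because many economically important taxa overlap
extensively in grain morphology, and within-species variability often
exceeds between-species differences.

`starchid` implements a quantitative identification workflow for this
setting: a reference collection of measured grains from candidate species is
curated by discriminant self-classification, and unknown (archaeological)
grains are then assigned to species with posterior-probability confidence
bins, or flagged as matching each other rather than any reference species.

## The data model

Each grain is described by 15 variables. Nine are quantitative: maximum and
minimum length (µm), total perimeter (µm), total area (µm²), maximum and
minimum hilum-to-edge distance (µm), and three derived shape indices:

* compactness `cI = 0.282 * P / sqrt(A)` — a Gravelius-type ratio, ~1 for
  circular outlines, larger for irregular ones;
* elongation `eI = l_max / l_min >= 1`;
* centricity `ceI = d_max / (d_max + d_min)` in `[0.5, 1]` — 0.5 for a
  centric hilum, approaching 1 as the hilum migrates to the margin.

Six are qualitative: 2-D outline shape (7 levels), hilum type
(non-visible/closed/open), fissure presence, fissure shape (7 levels),
pressure facets (6 levels), and extinction-cross style
(straight/curved/wavy). Lamellae are recorded but excluded from the feature
vector. Indices are binned into qualitative categories by rounding to two
decimals (half away from zero) and cutting at the conventional boundaries
(compactness: 1.00 / 1.25; elongation: 1.00 / 2.00 / 3.00; centricity:
0.60 / 0.70). The rounding rule is a design decision: the published category
bounds are two-decimal labels of contiguous intervals, and rounding first
makes the bins total and order-preserving on all attainable values.

Qualitative traits are coded as small ordinal integers in the order the
levels are conventionally listed ("absent" always 0), and the mixed matrix
is z-scored column-wise (sample SD) so all 15 variables carry equal weight.
Ordinal coding rather than one-hot is deliberate: it preserves the
15-column structure of a single mixed spreadsheet, which is how this type
of analysis is done in practice; the cost is an artificial metric on
unordered levels, which the user should keep in mind when editing code
tables (overridable through the YAML `encoding:` section).

## The classifier

The core is a pooled-covariance linear discriminant model
(`grain_lda()`), written out explicitly rather than delegated, because the
reported quantities — linear classification-function values, squared
Mahalanobis distances, and posteriors — are the scientific output:

* pooled within-group covariance `Sigma = sum_k (n_k - 1) S_k / (n - K)`;
* linear score `score_k(x) = m_k' Sigma^-1 x - m_k' Sigma^-1 m_k / 2 + log pi_k`;
* squared distance `d2_k(x) = (x - m_k)' Sigma^-1 (x - m_k)`;
* posterior `pi_k exp(-d2_k / 2)` renormalized, computed in log space.

Priors default to equal: the reference design is approximately balanced by
construction and distance-dominated posteriors match the reporting
convention of this workflow; proportional priors are a flag away. Ranking
is done on the linear scores (identical ordering to posteriors, immune to
underflow); exact ties resolve by group name. A singular pooled covariance
is an error by default; an optional ridge `Sigma + lambda I`
(`ridge = 1e-8` is a sensible value) is available and logged whenever
applied, since near-constant categorical codes in small collections can
degenerate.

## The two-step identification pipeline

`starch_identify()` runs the full procedure:

1. scale the reference matrix; fit the discriminant model on all reference
   grains;
2. classify the reference by resubstitution and keep exactly the grains
   whose prediction equals their species — the curated subset. Filtering by
   resubstitution (not cross-validation) is deliberate: the subset is meant
   to be the self-consistent core of the library, and kept grains are by
   construction classified perfectly by the full model;
3. refit on the curated subset pooled with the unknowns, which enter as a
   single extra group ("Archeo"). This lets an unknown match other unknowns
   better than any reference species — the signature of a taxon missing
   from the library;
4. classify every unknown across the K+1 groups, reporting the two best
   groups with score, squared distance and posterior;
5. bin by posterior: secure (> 0.90 to a species), archeo-matched (> 0.90
   to Archeo), probable (0.80–0.90), unassigned (< 0.80); thresholds are
   configuration;
6. optionally tabulate assigned species per source artifact.

Unknowns are scaled with reference-fitted parameters by default; pooled
scaling is available (`scaling = "pooled"`) because either reading of
"scaling the reference and archaeological matrices" is defensible. Unknowns
are classified by resubstitution (each contributes to the Archeo mean and
the pooled covariance); a leave-one-out variant is provided
(`method = "leave-one-out"`). The resubstitution default reproduces the
observed behavior that clustered unknowns can win their own group with
posterior near 1 — note the corollary, verified in the tests: if *all*
unknowns come from one species, the Archeo centroid coincides with that
species and the posterior splits between the two. That is a property of
the design, not a defect.

## The synthetic-data generator

No raw reference matrix is publicly deposited for this kind of collection,
so the package ships a generator (`species_profile()`,
`generate_reference()`, `generate_unknowns()`, `degrade()`) whose defaults
emulate the published study design: 13 species, 98–200 grains each, 1598
grains in total.

Grains are generated geometry-first: maximum length is lognormal (sizes are
positive and right-skewed, as starch size data are), the width ratio is a
beta variate, area is `pi/4 * l_max * l_min` times lognormal noise,
perimeter is the Ramanujan ellipse approximation times noise, and the hilum
offset is a beta eccentricity bounded so `d_min <= d_max <= l_min / 2`.
Indices are then *derived*, never sampled, so every generated grain
satisfies the data-model invariants by construction. Categorical traits are
sampled from per-species probability tables, independently of size (no
published evidence of dependence). Fissure shape implies fissure presence,
keeping those two columns consistent.

Interspecific overlap is controlled by blending pairs of profiles toward
their midpoint (`apply_overlap()`: level 0 = unchanged, 1 = the pair shares
one profile). The packaged `default13.yaml` library was calibrated once,
during development, so that full-reference discriminant self-classification
lands near 78% (observed 74–78% across seeds) with the
*Inocarpus-fagifer*-like / *Ipomoea-batatas*-like pair below 50% precision —
mirroring the qualitative structure of a real mixed collection. This is a
calibration property of the generator, not a reproduction of any measured
collection: the raw data behind the published per-species summaries are not
available, so agreement claims are limited to marginal structure.

A second programmatic library, `separated_profiles()`, produces
well-separated species (wide size spacing, tight dispersions,
near-deterministic distinct categorical traits; pairwise Mahalanobis
distances between centroids above 6). It defines the regime in which the
pipeline should recover essentially every unknown securely, and the test
suite holds it to ≥95%. Two cautions discovered while building it are worth
recording: (i) with near-deterministic categorical tables, a rare
off-majority draw is a large Mahalanobis outlier, occasionally costing a
secure assignment — real morphometric data behave the same way when a trait
is "fixed" in a species; (ii) fissure tables must leave both presence
states reachable in every species, otherwise the presence indicator
degenerates to a constant column and the pooled covariance is singular at
small n.

What passing tests on synthetic data do **not** show: robustness to
measurement error models of real microscopy (operator bias, pixelation),
taphonomic damage beyond random removal, or dependence between size and
qualitative traits. The generator is a structural emulator, not a
photorealistic simulator.

## Exploratory layer

`fit_pca()` eigendecomposes the correlation matrix (covariance of z-scores),
with a deterministic sign convention (dominant loading positive).
`grow_tree()` is a small greedy Gini CART with explicit determinism: ties in
impurity gain break to the lowest variable index, then the lowest
threshold; stopping is governed by `max_depth = 6` and `min_leaf = 5`
(defaults chosen as conventional values — the published tree's stopping rule
is not recoverable, so node counts are descriptive, not targets).
`split_train_validation()` stratifies 75/25 by class with largest-remainder
apportionment. Support-vector machines and random forests are deliberately
out of the core: the identification result flows only through the
discriminant path, and external classifiers would add surface without
anchored output.

## Numerical choices

* Posteriors in log space; ranking on linear scores (underflow-proof).
* Singularity detected by reciprocal condition number (`rcond < 1e-12`),
  not by Cholesky failure alone.
* Index rounding: half away from zero with a 1e-8 guard against binary
  representation error.
* Stratified splits clamp every class to at least one member on each side.
* Problem sizes in the test suite and acceptance script (e.g. 13 species x
  100 grains for recovery, 1e5 points for the closed-form error-rate check,
  10 seeds for the calibration band) were chosen as the smallest sizes at
  which the checked properties are statistically unambiguous.

## Known limitations

* Ordinal coding imposes an arbitrary metric on unordered categorical
  levels; distances between codes are not biologically meaningful.
* Equal-covariance (LDA) is an approximation; strongly size-divergent
  species violate it, which is partly why reference curation matters.
* The confidence thresholds (0.90/0.80) are conventions, not calibrated
  error rates; binned posteriors inherit all assumptions above.
* The generator cannot reproduce unpublished covariances between variables;
  only marginal summaries are emulated.
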