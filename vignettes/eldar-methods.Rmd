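---
title: "Latent methylation signatures of aging: model, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent methylation signatures of aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eldar)
```

## The analysis in one paragraph

The package pools beta-value matrices from four kinds of cohorts — donor-age
tissue series, serial fibroblast passaging (cumulative population
doublings, cPD), OSKM-reprogramming time courses (days of
Oct4/Sox2/Klf4/c-Myc expression), and an untimed transformation
contrast — and decomposes the pooled, row-centered matrix by SVD. Each
principal component's score is correlated with time within each dataset;
components are then classified as *shared* (up with age and cPD, down with
reprogramming), *refractory* (up with age and cPD, not strongly inverted
by reprogramming), or unclassified. The fitted loadings are a reusable,
unsupervised signature: new cohorts are projected onto them, and the most
extreme loading CpGs are characterized by annotation enrichment and by
overlap with published clock CpG lists.

## Decomposition and projection

`fit_eldar()` centers each CpG by its training mean and takes the thin SVD
of the centered sample × CpG matrix. No variance scaling is applied: the
decomposition is centered, unscaled PCA, so CpGs with larger methylation
variance contribute more, which is the convention for methylation PCA.
Explained variances are `d_k^2 / (n - 1)`; in tests they are checked
against an independent eigendecomposition of the sample covariance to
1e-8, and the retained scores-times-loadings product reconstructs the
centered matrix exactly when all components are kept.

Two conventions are deliberate choices rather than mathematical facts:

- **Sign orientation.** An SVD's column signs are arbitrary. When a sample
  sheet is supplied, each component is flipped so its score correlates
  non-negatively with donor age in the tissue-aging training cohort, making
  "increases with aging" a convention of the fitted object.
- **Component identity.** Components are numbered by explained-variance
  rank, but downstream stages address them by their *classification*
  (shared / refractory), never by index: a different training pool need not
  place the refractory signal at the same rank. In the default synthetic
  design the refractory factor often carries more pooled variance than it
  would in real data, so it can even outrank the shared one.

`project_cohort()` restricts to CpGs shared with the model, subtracts the
training means, and multiplies into the loading rows. CpGs absent from a
cohort (or missing in a sample) contribute zero, which is exactly
imputation at the training mean. Scores are *not* rescaled by coverage:
rescaling would change a score's units as coverage varies and silently
mix variance compensation into a linear projection. Instead the per-sample
coverage fraction is reported and a warning fires below 50% coverage.

Pooling (`intersect_and_pool()`) keeps only CpGs present and non-missing
in every cohort, because complete-case rows keep the SVD exact; the CpG
order is canonicalized lexicographically (C locale) so loadings are
byte-reproducible across runs and platforms. No cross-cohort
normalization or batch correction is applied beyond pooling itself — the
pipeline consumes already-normalized betas.

## Screening and classification

Correlations are Pearson throughout (the trends screened for are linear
score-versus-time relationships), with two-sided p-values from the t
transform on n − 2 degrees of freedom. One engine
(`pearson_time_cor()`) serves both the training screen and the
validation-stage associations; a test asserts the two code paths return
identical tables. Untimed cohorts (transformation) are excluded from the
screen. The classification thresholds default to `t_hi = 0.5` and
`t_lo = 0.3`: strong evidence is required in all three timed domains to
call a component shared, while refractory requires only moderate
positive aging/passaging trends plus the *absence* of a strong negative
reprogramming trend. Both thresholds are user-configurable because they
are reading conventions, not estimated quantities; the dichotomy itself,
not the exact cutoffs, is the scientific claim being operationalized.

The age × sun-exposure interaction model (`fit_age_sun_interaction()`)
is ordinary least squares of a projected score on
`[1, age, sun, age·sun]` with exposure coded protected = 0 / exposed = 1.
The coding is recorded in the fitted object because the interaction
coefficient's sign flips if the coding flips. No multiple-testing
correction is applied; the model reports raw p-values.

## What the synthetic generator emulates

`simulate_cohorts()` plants exactly the structure the analysis is designed
to find, on the logit scale:

```
beta_ij = plogis(mu_i + w1_i f1_j + w2_i f2_j + batch_d(j) + eps_ij)
```

- `f1` (shared): rises linearly with age (20–90 y) and cPD (5–60), falls
  linearly over reprogramming days (0–28), and shifts upward in
  transformed samples.
- `f2` (refractory): rises with age and cPD, follows a piecewise-linear
  rise to a peak at day 15 of reprogramming followed by linear reversion
  of 80% of the rise — the simplest trajectory with a transient rise and
  partial reversion beginning around the maturation phase — and shifts
  *downward* in transformed samples.
- `w1`, `w2`: sparse loadings (20% nonzero, standard normal), `mu` a
  N(0, 1) baseline logit, `batch` a per-dataset scalar offset
  (sd 0.05), `eps` i.i.d. N(0, 0.2) latent noise, plus N(0, 0.05)
  per-sample jitter on the factor trajectories.

Noise is added *before* the logistic squash, so betas are strictly inside
(0, 1) by construction, and with all noise terms at zero the betas equal
the squashed ledger reconstruction bit-for-bit.

Three generator choices deserve justification:

- **Effect sizes** default to `a1 = (1, 1, 1.5, 1)` and
  `a2 = (1.2, 0.6, 1.5, −1)` across (tissue_age, passaging,
  reprogramming, transformation). The magnitudes express that
  reprogramming moves the shared signal more than a lifetime of aging
  does, and that the refractory signal's passaging trend is moderate
  rather than strong. No published effect sizes exist for these latent
  signals; these are design choices of the simulator, not estimates.
- **The transformation shift of `f2` is negative** (opposite to `f1`).
  Transformed-versus-control cells are reported to vary along both latent
  axes but with no stated direction, so the direction is free; choosing
  opposite shifts keeps the two planted factors close to orthogonal in
  the pooled sample space. With same-direction shifts the factors'
  pooled correlation rises to ~0.35–0.55, and no orthogonal rotation (which
  is what PCA returns) can then correlate highly with *both* planted
  factors — the recovery ceiling drops to ~0.8 before any noise. This is
  a genuine property of factor geometry, not a software artifact, and the
  simulation should not build in an impossibility.
- **Effects sit in the quasi-linear band of the logistic.** Loading-scale
  1 times factor ranges ~1 keeps most logit perturbations within ±1.5,
  where the squash is near-linear. Much larger effects make the strong
  factor's nonlinear harmonics (e.g. an f1-squared pattern, which mimics
  the refractory rise-then-revert shape in the reprogramming cohort)
  bleed into the other components.

The annotation generator couples island-relation and chromatin-state
labels to the *loading class* of each CpG (dominant nonzero loading and
its sign; CpGs with no nonzero loading are background). Default
probabilities qualitatively echo the expected biology — methylation
gainers concentrated in islands/shores and bivalent promoters, losers in
open sea, enhancer and quiescent states — and are fully configurable,
including a null (equal-probability) setting under which top-loading CpGs
match the background composition within binomial error.

What the generator does **not** emulate: probe-level artifacts (intensity,
detection p-values, dye bias), probe-specific batch effects (batch is a
single scalar per dataset, as the latent model states), genomic
coordinates, correlated CpG blocks, cohort-specific missingness patterns,
nonlinear aging trajectories, or realistic variance shares (the planted
factors carry far more pooled variance than any real latent aging signal
would). Passing recovery tests therefore shows the pipeline is correct
and well-conditioned under its own assumptions — not that real EPIC-array
cohorts would yield signals this clean, nor that the published cohort
correlations are reproduced.

## Population-doubling bookkeeping

`cumulative_pd()` implements
`PDL = previous + 3.32 · log10(collected / seeded)`. The log is base 10:
3.32 ≈ 1/log10(2), so a 2-fold expansion adds one doubling, which is the
only reading under which the constant is coherent. Contractions are
permitted (with a warning) since dying cultures do shrink. Senescent
samples get an extrapolated cPD — PDL at senescence onset plus the line's
average pre-senescence doublings/day times the days since onset — because
their measured doubling level no longer advances.

## Enrichment and clock-overlap conventions

- "Top k" CpG sets are selected by *signed* loading, separately for the
  positive and negative directions, because gainers and losers of
  methylation are characterized separately. Boundary ties break by
  lexicographic CpG ID for determinism.
- The enrichment background is the pooled-analysis CpG universe (the
  annotation's full CpG set), not an array manifest. Background
  self-enrichment is exactly 1 by construction. No enrichment p-values
  are computed by default; folds are the reported statistic.
- The per-clock overlap percentage divides the summed per-set overlap
  counts by the clock's own size — the only denominator convention that
  reproduces all of the published worked-example percentages
  (15/391 → 3.8%, 4/71 → 5.6%, 4/513 → 0.8%). Pairwise clock-to-clock
  percentages are ambiguous (either clock's size can serve as
  denominator), so the package reports raw symmetric counts with sizes on
  the diagonal and leaves normalization to the caller.
- `loading_density()` complements fixed-size overlap with a
  distributional view: percentile ranks of clock CpGs' absolute loadings
  against all model CpGs, plus a two-sample Kolmogorov–Smirnov statistic
  against the non-clock background.

## Numerical and degenerate-input policy

- Components whose singular values are numerically zero (relative
  threshold `max(d_1, 1) · 1e-12 · sqrt(n)`) are dropped with a warning;
  a constant matrix yields zero components, zero scores, zero variance.
- Orthonormality and reconstruction are tested to 1e-8; projection
  identities to 1e-10; OLS against a hand-solved normal-equations oracle
  to 1e-10.
- Zero-variance scores or times yield missing correlations with a
  warning rather than an error in the screen, but validation-stage
  `score_time_correlation()` insists on ≥ 3 timed samples per group.
- Singular interaction designs (single exposure level, constant age)
  fail with the collinear column named.
- All randomness flows from explicit integer seeds. The pipeline expands
  its root seed by fixed offsets (cohorts `seed`, annotation `seed + 1`,
  synthetic clock `seed + 2`) so stages can be rerun in isolation;
  identical configuration and seed give byte-identical output bundles,
  which is asserted by checksum in the tests.

## Problem sizes

The default simulated design is 2,000 CpGs × 80 samples (20 per domain),
which fits the whole pipeline in well under a second and makes
property-style loops (20-seed clock-density comparisons, 100-replicate
interaction-sign recovery) cheap; unit tests use a 300-CpG, 40-sample
variant of the same design. These sizes are choices of the test design:
the implementation is dimension-agnostic and the SVD path handles
EPIC-scale matrices (~850k CpGs) limited only by memory.

## Known limitations

- Linear signatures only: no nonlinear embeddings, so genuinely nonlinear
  aging trajectories appear as linear approximations spread over several
  components.
- No probe-reliability weighting, no M-value training mode by default,
  and no cross-cohort batch correction — heterogeneous real cohorts may
  need upstream harmonization the package deliberately does not do.
- Post-mitotic plateau behavior (scores leveling off after senescence or
  terminal differentiation) is not modeled; if a sample sheet encodes
  phases, per-phase correlations are the supported analysis.
- The classification thresholds are conventions; near-threshold
  components should be inspected via `autoplot()` rather than trusted.
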