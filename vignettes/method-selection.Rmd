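---
title: "Selecting an imputation method for mixed-type trait data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting an imputation method for mixed-type trait data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitimpute)
```

## Overview

`traitimpute` chooses an imputation method for a specific
species-by-trait table by rehearsal: it deletes values it actually
knows, asks each candidate method to restore them under several
missingness mechanisms, and selects the configuration that restores
them best. The premise is that no imputation method is best in general —
performance depends on the data types present, the correlation structure
among traits, the strength of phylogenetic signal, and the mechanism
generating the missingness — so the selection should be an experiment on
the dataset at hand rather than a literature default.

This vignette documents the model and its assumptions, the parameters
that matter, the synthetic data generator used throughout the tests, and
the numerical choices made where the procedure leaves room.

## The data model

A `trait_table` couples unique species identifiers with typed columns:
continuous, count (non-negative integers), binary, or multi-categorical
(declared category labels). Missingness is explicit (`NA`), and each
trait carries two per-column policies:

* `transform`: `natural_log` traits are log-transformed before
  imputation (distance-based methods are sensitive to the range of the
  data; size and clutch traits are right-skewed). The transform requires
  strictly positive values, so a signed trait such as a latitude
  centroid declares `none` — one cannot log a negative number, and
  centering tricks would change the trait's meaning. Counts are modelled
  on the log scale by the regression-based imputers; back-transformed
  counts are reported non-integer unless rounding is requested, because
  evaluation happens on the model scale.
* `mnar`: how a worst-case deletion targets this trait (which tail of
  the distribution, or which category).

The near complete-case construction keeps the largest row subset with
per-trait missingness at most 10% in which every incomplete species
still has at least three observed other traits. When the 10% bound is
violated, rows with the most missing cells are dropped first, ties
broken by species identifier: the constraint is stated on the outcome,
not the algorithm, so a deterministic greedy rule was chosen.

Dataset-construction screens are provided but never applied silently:
`detect_severe_outliers` flags values strictly above Q3 + 3·IQR (such
values should be verified against primary sources, not deleted), and
`screen_class_imbalance` excludes categorical traits whose modal
category exceeds 90% of observations — at exactly 90% the trait is
kept, reading "more than 90%" strictly.

## Missingness simulation

**MCAR.** For each trait, exactly `round(p * n)` observed cells are
masked (rounding half away from zero, so counts do not depend on the
parity of p·n). Pre-existing missing cells count toward neither the
target nor the pool: p is *additional* missingness. Within a replicate
the plans are nested across proportions — the 20% plan contains the 10%
plan — so error differences across proportions reflect the extra
missingness, not which species happened to be drawn.

**MAR.** A logistic regression of the missingness indicator on the other
traits is fitted to a *reference* table that carries real missingness
(typically the full, unfiltered dataset the analysis table was distilled
from). Predictors are screened at α = 0.05 and the model refitted on the
survivors; a trait with no significant predictor is ineligible for MAR
simulation and simply casts no MAR vote. To use the fitted covariate
dependence while still controlling the overall amount of missingness,
the intercept is shifted by a scalar (solved by root-finding) so the
expected number of masked cells equals `round(p * n)`, and cells are
drawn by independent Bernoulli trials. The calibration target defaults
to p = 0.20 — inside the range spanned by the MCAR settings — and is
configurable; the amount of missingness a MAR rehearsal should target is
a judgement call, not something the data dictate.

**MNAR.** Numerical traits lose exactly the observed cells at or below
the 0.10 quantile of the chosen tail (lower, upper, or
`center_on_zero`, which ranks by absolute value — emulating the loss of
near-equatorial records for a latitude trait). Categorical traits lose
one named category; the default is the *entire* category (fraction 1,
with an optional cap), the most extreme reading of single-category
deletion and the harder test: after deletion the observed data contain
no evidence the category exists, so methods are being tested exactly
where imputation is most dangerous. A consequence accepted here is that
single-class degeneracies arise (see Numerical choices).

Every plan records its mechanism, proportion, replicate and seed, and
serializes to CSV so any replicate can be replayed bit-exactly.

## Candidate imputers

All four imputers share two contracts: observed cells are never altered,
and identical (table, configuration, seed) gives a bit-identical result.

* **Mean/mode** is the baseline; ties between modal categories break to
  the lexicographically smallest label for determinism. It has no
  phylogenetic variant: appending eigenvector predictors cannot change a
  marginal mean or mode, and the combination design counts accordingly.
* **k-nearest neighbour** ranks donor rows (rows observed for the
  target) by Gower dissimilarity over the target's screened predictors
  plus any eigenvector columns: numeric contributions |xᵢ − xⱼ|/range,
  categorical mismatch 0/1, averaged over components available in both
  rows. The imputed value is the median (numerical) or mode
  (categorical) of the k = 5 nearest donors; distance ties break by
  donor order. A row observing none of its screened predictors falls
  back to all available columns, then to the all-donor aggregate.
* **Iterative random forests** (the missForest algorithm): initialize by
  mean/mode, visit traits in order of increasing missingness, refit a
  forest per trait on originally observed rows against the current
  completions, re-predict missing cells, and stop when the combined
  difference criterion (normalized squared change over numerical imputed
  cells; proportion of changed categorical imputed cells) rises for
  every family present, returning the previous iterate. Defaults are the
  published algorithm's: 100 trees, at most 10 iterations, √p / p∕3
  feature subsampling for classification/regression.
* **Chained equations with predictive mean matching**: m = 5 chains,
  each initialized with random draws from the observed values and
  cycled 5 times over the incomplete traits. Continuous and count
  traits use type-0 PMM — a linear fit on the observed rows, a donor
  pool of the 5 observed values with fitted means closest to the
  missing row's prediction, one donor drawn uniformly — so imputed
  values are always observed values of the trait and cannot leave its
  range. Binary and multi-categorical traits draw from fitted logistic
  and multinomial-logit probabilities. Chains are pooled by mean
  (numerical) or mode (categorical). Parameter uncertainty is *not*
  propagated (no posterior draw before matching): the pipeline pools to
  a single value anyway, and the simplification keeps the imputer
  deterministic given its seed. This is a deliberate deviation from
  fully proper multiple imputation and is the reason no Rubin's-rules
  variance pooling is offered.

Auxiliary predictors are screened per target by single-covariate
regressions with the family matched to the target's type (linear,
Poisson, logistic, polytomous logistic), keeping auxiliaries with any
coefficient p-value below α = 0.05. Count targets are screened by
Poisson regression on the count scale, so screening runs before the log
transform. Eigenvector columns bypass the screen: they are appended
wholesale whenever a phylogeny source is configured, matching how
eigenvector predictors are used in practice, and whether to screen them
is genuinely open — the choice is centralized in `predictors_for()` if a
user wants the other behaviour.

## Phylogenetic information

Eigenvectors come from a principal coordinates analysis of the patristic
distance matrix (Gower double-centering of −½·D∘D). The smallest k
axes whose cumulative share of the positive-eigenvalue sum reaches the
threshold (default 0.65) are retained; dropping the last retained axis
would fall below the threshold. Negative eigenvalues — possible on
non-ultrametric inputs — are discarded from numerator and denominator
alike, the convention that keeps variance fractions interpretable as
shares of representable variance. Trees are expected ultrametric
(dating happens upstream); ultrametricity is checked at a relative
tolerance of 1e-3 and warned about, not enforced. This is a PVR-style
construction: no Ornstein–Uhlenbeck branch-length steepening is applied
before the PCoA, which keeps the eigenvectors a pure function of the
tree's path-length geometry.

Phylogenetic signal estimators are included because the payoff of
phylogenetic imputation should track signal strength:

* **Pagel's λ** multiplies the off-diagonal of the Brownian covariance
  matrix, leaving tip variances unchanged; the mean and rate are
  profiled out analytically and λ maximized on [0, 1] by bounded search
  (tolerance 1e-6), with the endpoints checked explicitly since the
  likelihood is often maximized at a boundary. The no-signal test uses
  the boundary mixture ½χ²₀ + ½χ²₁ for the likelihood ratio, the correct
  null for a parameter tested at the edge of its space. A star tree
  makes C(λ) independent of λ; that input returns an explicit
  unidentifiable flag, never a number.
* **Fritz & Purvis' D** scales the observed sum of character changes
  (ancestral values by equal-weight averaging of descendant values,
  absolute differences summed over edges) between the mean under
  tip-label shuffles (D = 1) and under threshold-Brownian simulations at
  the observed prevalence (D = 0), with 1000 draws of each by default
  and tail probabilities against both nulls.

## The synthetic generator

`simulate_study()` emulates the structure of a reptile life-history
table: a Yule tree (default 152 tips — a realistic near complete-case
size for a well-sampled clade) and seven traits — two log-normal size
traits (latent correlation 0.9), two strictly positive right-skewed
clutch counts via 1 + Poisson(exp(·)) (correlation 0.7 between them, 0.4
with sizes; a minimum clutch of one egg is the realistic floor), a
signed weakly correlated latitude centroid, a rare binary insularity
trait (20% prevalence), and a three-level activity-time trait thresholded
at the 0.55/0.85 latent quantiles, giving one dominant (55%) and one
rare (15%) category as is typical of activity data. Latents follow
Brownian motion with per-trait λ-rescaling applied *before* mixing by
the correlation matrix, so equal-λ settings have exactly the requested
marginal signal. Categorical traits are produced by rank thresholds, so
their prevalences are controlled exactly. Up to 10% pre-existing MCAR
missingness is placed with rejection sampling so the near complete-case
constraints still hold. `simulate_reference()` adds covariate-driven
missingness (log-odds slope −1 per SD of body size: small species are
less studied) to a larger companion table, giving the MAR models
something real to recover.

What the generator does *not* emulate: gene-tree discordance (alternate
"gene trees" must be supplied as separately simulated or perturbed
trees), measurement error, taxonomic sampling bias, non-stationary
evolution, and trait-dependent diversification. Passing tests therefore
demonstrate that the machinery is correct and behaves as theory predicts
on data with known structure — not that any particular real dataset is
imputable.

## Evaluation and selection

MSE is computed on the model (transformed) scale, where the imputers
operate — a flag enables original-scale evaluation for users who want
errors in natural units. Only cells that were deliberately masked *and*
have an observed true value enter the metrics; per-trait values are
averaged over cells within a replicate, then over replicates (the two
orders agree when evaluable-cell counts are constant across replicates).
Masking is shared across method/source combinations within a replicate —
replicate seeds derive from (master seed, mechanism, proportion,
replicate) only — so methods are always compared on identical
missingness.

The majority vote considers MAR first (the mechanism most like real
trait missingness), with each eligible trait voting for the combination
with its lowest mean error; exact vote ties are re-voted under MNAR,
then MCAR (votes summed over proportions), and a tie surviving all
three mechanisms is an error rather than an arbitrary pick. "Performing
similarly" is operationalized as an *exact* vote tie; near-ties appear
in the recorded trace but do not trigger tie-breaking, since any
near-tie margin would itself be an arbitrary constant. Within a trait's
vote, an exact error tie resolves to the alphabetically first
combination, again for determinism.

The dataset comparison report uses Student-t 0.95 confidence half-widths
(t quantile at N−1 df × SE), the convention that reproduces standard
summary-table arithmetic at these sample sizes.

## Numerical choices and degenerate inputs

* Quantiles (outlier screen, MNAR tails) use linear interpolation of
  order statistics (type 7), the default in mainstream numeric stacks.
* All count targets round half away from zero, fixed for
  reproducibility across platforms.
* Seeds: every stochastic operation takes an explicit seed; internal
  streams derive from a string-keyed 32-bit hash, so adding a method
  never shifts another method's stream.
* MNAR single-category deletion leaves a categorical trait single-class
  among observed cells. Model-based imputers then have exactly one
  consistent prediction — the remaining class — and that is what the RF
  and chained-equations imputers produce (PFC for the deleted category
  is then 1 by construction; that *is* the measured cost of extreme
  bias). Logistic-style separation in MAR model fitting is detected by
  coefficient blow-up and the offending predictor dropped with a
  warning.
* A target whose screen retains no auxiliary falls back to all other
  traits rather than failing: degrading toward an unscreened model is
  preferable to aborting a replicate.
* Failures inside one (setting, replicate) are recorded and excluded
  from aggregation rather than aborting the study; the failure table is
  part of the fitted object.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest
sizes chosen to exercise every code path with comfortable statistical
margins: signal-estimator recovery uses a 100-tip tree with 200 (λ) and
100–60 (D) trait replicates; mechanism checks use 100-species tables
with up to 500 masking replicates; the end-to-end strategy demonstration
uses 100 tips, seven traits, three methods with and without one tree,
MCAR at 0.10/0.20 plus MAR and MNAR, and 10 replicates. The full
four-method, four-tree, 100-replicate design (96 settings, 9,600 runs)
is enumerated and counted rather than executed; nothing in the code
limits a user from running it.

## Known limitations

* Multiple imputation is collapsed to a single table; the m per-cell
  values are retained for inspection but no pooled-variance inference is
  offered.
* The MAR missingness model is fitted once per trait and reused across
  replicates (draws differ by seed); refitting per replicate would mix
  model-estimation noise into the comparison.
* Eigenvector extraction is PVR-style PCoA; evolutionary-model-based
  eigenfunction methods (OU steepening) are out of scope.
* D is defined for binary traits only; multi-level categorical traits
  must be decomposed into indicator traits by the user.
* Little's test or other mechanism diagnostics on real data are out of
  scope: the strategy *assumes* the mechanisms and measures consequences.
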