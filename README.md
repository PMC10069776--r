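# traitimpute

Simulation-based selection of a missing-data imputation method for
mixed-type species-trait tables, with optional phylogenetic information.

## The problem

Species-by-trait tables — body sizes, clutch sizes, range centroids,
activity patterns — are rarely complete, and restricting an analysis to
complete cases discards most of the data while biasing what remains.
Imputation can recover that information, but no single imputation method
wins everywhere: performance depends on the mix of trait types
(continuous, count, binary, multi-categorical), on *why* values are
missing, and on how much phylogenetic signal the traits carry. This
package implements a real-data-driven strategy for choosing a method for
a *given* dataset, for researchers in comparative biology, macroecology
and conservation who need defensible imputations rather than a generic
recommendation.

## The strategy

Starting from a near complete-case table (per-trait missingness ≤ 10%,
and every incomplete species observed for at least three other traits),
the strategy runs four steps:

1. **Simulate missingness** in the near complete-case table under three
   mechanisms: MCAR (random deletion at nested proportions
   p = 0.10, 0.20, 0.30, 0.40, each plan a superset of the previous),
   MAR (Bernoulli deletion with probabilities from a logistic model of
   the missingness indicator fitted to a reference dataset, with the
   intercept calibrated so the expected count equals round(p·n)), and
   MNAR (deleting the 10th-percentile tail of a numerical trait, or one
   whole category of a categorical trait).
2. **Impute** each replicate with every candidate configuration:
   mean/mode, k-nearest neighbour on Gower dissimilarities, iterative
   random-forest imputation, and chained equations with predictive mean
   matching (PMM for continuous/count traits, logistic and polytomous
   logistic draws for categorical ones, m chains pooled by mean/mode) —
   each with and without phylogenetic eigenvectors. Eigenvectors are the
   leading axes of a principal coordinates analysis of the tree's
   patristic distance matrix, retaining the smallest set of axes that
   explains ≥ 65% of the (positive-eigenvalue) variance. Auxiliary
   predictors are screened per target trait by single-covariate
   regressions (linear / Poisson / logistic / polytomous by target type)
   at α = 0.05; numerical traits are natural-log transformed where
   positive.
3. **Score** each run over the deliberately masked cells only:
   MSE = mean (imputed − truth)² for numerical traits (model scale),
   PFC = proportion falsely classified for categorical traits, averaged
   over replicates per setting.
4. **Vote**: under MAR each trait votes for the (method, phylogeny)
   combination with the lowest mean error; the combination with most
   votes is the best-suited method, with exact ties re-voted under MNAR,
   then MCAR. The winner is applied to the original incomplete table and
   the result compared, trait by trait, against the original and
   complete-case data.

The benefit of phylogeny for one method/trait/mechanism is summarised by
the **error ratio** = error without phylogeny / error with phylogeny
(above 1: phylogeny helped). Phylogenetic signal itself is quantified by
Pagel's λ (profile maximum likelihood on [0, 1]) for continuous traits
and Fritz & Purvis' D (permutation- and simulation-scaled sum of
changes) for binary traits.

Because real squamate-scale data cannot ship with the package, a
synthetic generator produces trees (Yule / birth-death) and correlated
mixed-type trait tables with tunable per-trait phylogenetic signal,
pre-existing missingness, and a companion reference table with
covariate-driven (MAR) missingness.

## Worked example

```r
library(traitimpute)

study     <- simulate_study(n_taxa = 100, signal_lambda = 0.9, seed = 7)
reference <- simulate_reference(n_taxa = 400, signal_lambda = 0.9, seed = 8)

fit <- impute_strategy(
  study$table, trees = list(gene = study$tree),
  methods = c("mean_mode", "knn", "rf"),
  mcar_proportions = c(0.1, 0.2), n_replicates = 5,
  mar_reference = reference, seed = 42)
print(fit)
#> Real-data-driven imputation method selection
#>   100 species (near complete-case), 7 traits, 1 trees
#>   20 settings x 5 replicates = 100 runs (0 failed)
#> best-suited method: rf (phylogeny: gene)
#>   MAR votes: knn+gene=0, knn+none=0, mean_mode+none=0, rf+gene=3, rf+none=1
```

Under MAR, random forests with eigenvectors from the tree win the vote
for 3 of the 4 MAR-eligible traits, so `rf + gene` is selected without
tie-breaking. The mean categorical error ratio here is 1.17 — adding the
phylogeny cut classification error by about 17% on average, as expected
for traits simulated with strong signal. Applying the winner:

```r
application <- predict(fit, study$table)
print(application)
#> best-suited method applied to 100 species (rf + gene)
#>   per-trait missingness of the imputed subset:
#>     svl_female         0.05
#>     ...
```

`application$imputed` holds the completed table (original scale);
`application$comparison` tabulates N, min/max, mean, SE, 0.95 CI
half-width, variance and SD (or category frequencies) for the original,
imputed, and complete-case data so the effect of imputation on the
dataset's characteristics can be inspected directly.

A thin command-line front end over the same functions is provided in
`inst/cli/traitimpute.R` (subcommands `synth`, `eigenvectors`, `signal`,
`simulate-missing`, `impute`, `run-strategy`, `apply`, `config-init`).

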