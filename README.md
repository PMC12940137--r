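# microgradient

Downstream analysis of shotgun-metagenomics cohorts stratified into
**ordered risk groups**, asking whether microbiome features shift
*progressively* with risk rather than merely differing between diseased and
healthy. The motivating design is a type-2-diabetes family-history cohort
with four groups — 0, 1 or 2 affected parents, and diagnosed participants
(0 < 1 < 2 < D) — but any four-level ordered design fits.

## What it computes

**Taxonomic profiling.** Raw gene counts are rarefied to a common depth
(multivariate hypergeometric), length-normalised to within-sample
frequencies, and summarised per MetaGenomic Species (MSP) as the mean of
its 100 marker-gene frequencies, nulled when fewer than 10% of markers are
detected. Ecosystem metrics: richness, taxon aggregates, Gram+/Gram−
abundance ratio (with phylum-majority fallback for unannotated species) and
the oral-to-gut detected-species ratio.

**Enterotypes.** Dirichlet multinomial mixtures on genus counts, fitted by
EM (Minka fixed-point M-step), component count selected across restarts by
BIC (Laplace evidence available), components named EtF / EtB1 / EtP / EtB2
from their dominant genera; enterotype-by-group shifts tested with Fisher's
exact test (Monte-Carlo beyond 2×2).

**Functional potential.** A module is present in an MSP when ≥ 90% of its
ortholog components are covered by core genes, refined per sample with
detected accessory genes; module potential = summed abundance of carriers.
CAZyme families run through the same machinery as single-component modules.

**The dual-window gradient screen** — the package's core statistic. A
feature is a gradient marker only if its Spearman correlation with the
ordinal group code is significant (p < 0.05) with adequate effect size
(|rho| > 0.2) **both** excluding and including the diseased group, with
consistent sign; Benjamini-Hochberg q-values are computed within feature
family, and selected markers are re-validated by nested covariate-adjusted
models (group term F-test / multinomial LRT, Jarque-Bera residual
diagnostics).

**Diet.** Dietary patterns by varimax-rotated PCA of 28 food groups
(|loading| ≥ 0.30 flagged, patterns named from top loadings), the same
dual-window screen over dietary variables, and diet-vs-group attribution of
microbiota features by LMG relative-importance decomposition of R².

**Guilds.** Per-group co-abundance networks by stability selection (50%
prevalence filter, CLR transform, subsampled sparse correlation graphs at a
density tuned to mean edge stability ≈ 0.9, edges retained at ≥ 70%
frequency), greedy-modularity guild clustering, and tracking of focal taxa
co-membership across groups.

**Synthetic cohort generator.** Because this kind of cohort data is
access-restricted, `simulate_cohort()` produces all pipeline inputs with
planted ground truth — gradient species and modules, enterotype mixture
structure, correlated diet factors, covariate imbalance, a focal guild
block — so every stage is testable end to end.

## Worked example

```r
library(microgradient)

sim <- simulate_cohort(simulation_config(seed = 1))
ab <- prevalence_filter(sim$abundance)          # drop <10% prevalence
screen <- detect_gradient_markers(ab, sim$cohort)
print(screen)
#> Gradient screen: 283 features, 21 selected (dual-window criterion)
#>   feature rho_012    q_012 rho_012D   q_012D
#>  msp_0046  -0.392 2.19e-05   -0.602 3.35e-18
#>  msp_0077  -0.449 6.75e-07   -0.622 1.64e-19
#>  msp_0078   0.425 3.41e-06    0.516 2.89e-13
#>  msp_0104   0.487 3.49e-08    0.540 1.16e-14
#>  ...
```

Each row is one MSP: `rho_012` is its Spearman correlation with the group
ordinal over the non-diseased window (groups 0-1-2), `rho_012D` over all
four groups, with the within-family BH q-values; a negative rho means the
species declines as risk rises. At seed 1 the screen recovers all 20
planted gradient species among its 21 selections. The Gram+/Gram− ratio
falls along the planted gradient (per-group medians 0.74, 0.46, 0.50, 0.23
at this seed):

```r
round(tapply(gram_ratio(sim$abundance, sim$catalog),
             sim$cohort$group, median), 2)
#>    0    1    2    D
#> 0.74 0.46 0.50 0.23
```

The whole pipeline, writing per-stage tables and a manifest with input
hashes, parameters and seed:

```r
res <- run_pipeline(run_config(sim_config = simulation_config(seed = 1),
                               seed = 1), "run1")
```

## Package layout

- `R/` — implementation (profiling, enterotyping, modules, gradient
  screen, diet, guilds, pipeline, synthetic generator)
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (brute-force enumeration, direct likelihood
  optimisation, reference implementations)
- `vignettes/gradient-analysis.Rmd` — the methods vignette: models,
  assumptions, parameter choices, generator scope, limitations
- `inst/extdata/` — small plain-text reference tables
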