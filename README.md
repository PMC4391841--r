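# regjoint

Large-region joint association testing for quantitative traits.

Complex-trait heritability is thought to hide in many individually weak
SNP associations that aggregate over extended chromosomal regions. This
package is for statistical geneticists who want to (a) compare the
standard regional association models on an explicit generative haplotype
model, (b) quantify how non-additive a haplotype architecture is and what
that does to power, and (c) scan real PLINK-format genotype data with
sliding-window joint tests, estimate the total phenotypic variance
explained by candidate regions through permutation, and measure
enrichment of candidate loci among associated windows.

## The model

Over `m` biallelic SNPs, `k` haplotypes with frequencies `pi` generate
individuals by Hardy-Weinberg random mating; the trait is

```
Y = D beta + eps,   eps ~ N(0, 1)
```

where `D` is the n x k diplotype copy-count matrix and `beta` the
per-copy haplotype effects, so the genetic variance is
`sigma2_H = 2 (sum_i pi_i beta_i^2 - (sum_i pi_i beta_i)^2)`.
Five association models are fitted to the *unphased* genotypes `G = D H`:
additive (one allele-count column per SNP), pairwise interaction,
genotypic (3^m class indicators), haplotype probability (EM-phased
expected haplotype counts), and a Haseman-Elston variance component on
the GRM `Z Z'/m` with quadratic-form (weighted chi-square) testing. The
non-additivity of an architecture is
`tau' = tau / tau_max, tau = (sigma2_H - sigma2_G)/sigma2_H`, with
`sigma2_G` the variance the additive design captures in the population;
`tau_max` is computed in closed form as a generalized eigenvalue. Power
for the regression models uses the non-central F distribution with
non-centrality `n R^2 / (1 - R^2)`.

## Worked example

```r
library(regjoint)

# two SNPs, four haplotypes, frequencies chosen so pairwise r2 = 0
hs <- haplotype_system(rbind(c(0,0), c(0,1), c(1,0), c(1,1)),
                       pi = c(0.10, 0.30, 0.15, 0.45))
pairwise_ld(hs, 1, 2)$r2
#> [1] 6.847751e-32

# effects with haplotype variance 0.006 at half-maximal non-additivity
beta <- effect_path(hs, sigma2_H = 0.006, tau_prime_target = 0.5)
sys <- haplotype_system(hs$H, hs$pi, beta = beta)
nonadditivity(sys)
#> Non-additivity: tau = 0.5, tau_max = 1, tau' = 0.5 (sigma2_H = 0.006)

# analytic power of the 2-df additive test at the suggestive threshold
analytic_power_f(n = 5000, r2 = 0.006/1.006, df1 = 2, alpha = 5e-5)
#> [1] 0.8693157

# simulate the scenario and compare models
cfg <- scenario_config(sys, n = 5000, n_replicates = 200,
                       models = c("additive", "genotypic"),
                       alpha = 5e-5, seed = 1)
run_scenario(cfg)
#> Scenario result over 200 replicates (alpha = 5e-05):
#>      model mean_raw mean_adj    se_raw    se_adj power n_ok
#>   additive 0.003312 0.002913 0.0001235 0.0001235 0.265  200
#>  genotypic 0.005949 0.004356 0.0001429 0.0001431 0.325  200
```

Read the numbers as proportions of phenotypic variance: at `tau' = 0.5`
the additive model recovers about half of the generated 0.006 (its
population capture declines with non-additivity), while the genotypic
model's adjusted estimate sits near the genotype-expressible ceiling;
its raw estimate is inflated by its 8 fitted degrees of freedom. At
`tau' = 0` both models estimate 0.006 without bias.

The empirical pipeline mirrors this on data: `read_plink()` +
`prepare_phenotype()` (log2, 1st-99th percentile trimming, joint
adjustment for covariates and known candidate SNPs) + `ld_prune()` +
`make_windows()` + `scan_windows()` for the genome scan;
`centered_scan()` and `offset_enrichment()` for distance profiles around
candidate loci; `permutation_adjusted_total()` for the permutation-
adjusted total variance explained; `roc_auc()` / `enrichment_or()` for
candidate-locus enrichment. A thin command-line front end with
subcommands `simulate | power | scan | center-scan | variance | enrich`
lives in `exec/regjoint` (an example scenario config ships in
`inst/extdata/`).

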