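---
title: "Large-region joint association: models, non-additivity and variance explained"
author: "regjoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Large-region joint association: models, non-additivity and variance explained}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regjoint)
```

## The problem

Genome-wide association studies test SNPs one at a time, yet for highly
polygenic traits much of the genetic signal is expected to come from many
weak effects aggregating over extended chromosomal regions, possibly with
*cis* interactions among them. `regjoint` provides the machinery to study
that regime: it compares five standard regional association models on an
explicit generative haplotype model, quantifies how "non-additive" a
haplotype architecture is, computes analytic and simulated power, and runs
an empirical sliding-window pipeline with permutation-based estimation of
the total phenotypic variance explained by candidate regions.

## The generative haplotype model

Over $m$ biallelic SNPs (alleles coded 0/1), a population carries $k \le
2^m$ distinct haplotypes, collected in a matrix $H_{k\times m}$ with
frequencies $\pi$. An individual is two independent haplotype draws
(Hardy–Weinberg random mating); the copy-count vector $d_i$ (summing to 2)
yields the unphased genotype row $g_i = d_i H$. The trait is

$$ Y = D\beta + \varepsilon, \qquad \varepsilon \sim N(0, 1), $$

with per-copy haplotype effects $\beta$. The genetic variance is available
in closed form,

$$ \sigma^2_H = \operatorname{Var}(D\beta)
   = \sum_i \beta_i^2\, 2\pi_i(1-\pi_i) - 4 \sum_{i<j} \beta_i\beta_j \pi_i\pi_j
   = 2\left(\textstyle\sum_i \pi_i\beta_i^2 - (\sum_i \pi_i\beta_i)^2\right), $$

so the total trait variance is $\sigma^2_H + 1$ and the population
proportion of variance explained is $\sigma^2_H/(\sigma^2_H + 1)$.

Because every population quantity is an expectation over the $k(k+1)/2$
diplotypes, the package computes them by exact enumeration
(`population_captured_variance()`), never by sampling — this is what lets
the enumeration serve as the oracle against which sampled estimates are
tested.

## The five association models

All regression models fit $Y = XB + \varepsilon$ by least squares on the
centered design, with a joint $F$-test of all genetic coefficients
(`fit_linear()`); they differ only in $X$:

* **additive** (`design_additive`): $X = G$, one allele-count column per
  SNP ($q = m$);
* **interaction** (`design_interaction`): $X = [G\ \Omega]$ with all
  $\binom{m}{2}$ pairwise genotype products;
* **genotypic** (`design_genotypic`): indicators of the $3^m$ multilocus
  genotype classes;
* **haplotype probability** (`em_haplotype_dosages`): $X = M$, the
  posterior-expected haplotype copy counts under Hardy–Weinberg, with
  haplotype frequencies estimated in-sample by EM;
* **variance component** (`grm`, `fit_vc_he`, `vc_pvalue`): genetic
  variance from the Haseman–Elston regression of squared pairwise trait
  differences on the genomic relationship matrix
  $\Gamma = ZZ'/m$ (normalized genotypes $z_{il} =
  (g_{il}-2\xi_l)/\sqrt{2\xi_l(1-\xi_l)}$), tested through the quadratic
  form $Q = y'\Gamma y$.

Two estimates of genetic variance are always reported: the raw in-sample
explained variance $\hat B'X'X\hat B / n$ and a small-sample-adjusted
version that subtracts the null expectation $(1-R^2)\,\mathrm{df}_1 /
(n-\mathrm{df}_1-1)$, mirroring the classical adjusted $R^2$. The adjusted
estimator is unbiased at the null and is the default summary in
simulations; the raw one is what an in-sample "variance explained" reader
sees. Both can be compared in any `scenario_result`.

### Numerical choices

Rank deficiency is handled by a pivoted QR with relative tolerance
$10^{-8}$: collinear columns are dropped, reported (`n_dropped`), and
$\mathrm{df}_1$ equals the retained rank, so windows with duplicated or
near-duplicated SNPs are fitted with honest degrees of freedom rather than
a pseudo-inverse. The EM phasing initializes at uniform frequencies over
the compatible haplotypes, works on distinct genotype classes (cost is
bounded by $3^m$, not $n$), stops at $\max|\Delta\hat\pi| < 10^{-8}$ or
1000 iterations, and guarantees a monotone log-likelihood. Missing
genotypes are mean-imputed per SNP before any design is built — never at
the I/O layer.

The null distribution of $Q = y'\Gamma y$ is a weighted sum of
$\chi^2_1$ variables with weights the eigenvalues of $\Gamma$ (computed
from the $m \times m$ cross-product $Z'Z/m$, which shares the nonzero
spectrum). The tail probability is evaluated exactly by the
Ruben–Farebrother mixture-series representation — valid here because the
GRM is positive semi-definite — accumulating mixture mass to within
$10^{-12}$, with a Kuonen saddlepoint approximation as fallback
(`wchisq_pvalue()`). A characteristic-function quadrature was considered
and rejected: with few SNPs the oscillatory integrand decays like
$u^{-1-m/2}$ and generic quadrature over $(0,\infty)$ is unreliable,
whereas the series is absolutely convergent.

On the $\Gamma = ZZ'/m$ scaling the Haseman–Elston slope converts to
genetic variance as $\hat\sigma^2_g = -\hat v_1/2$ on the trait-variance
scale; the raw $ZZ'$ convention is available behind the `scaling` flag of
`grm()`.

## Non-additivity

For a haplotype architecture $(\pi, \beta)$, let $\sigma^2_G$ be the part
of $\sigma^2_H$ recoverable by the additive design in the population. The
non-additivity fraction is $\tau = (\sigma^2_H - \sigma^2_G)/\sigma^2_H$;
normalizing by its maximum at the given frequencies gives $\tau' =
\tau/\tau_{\max} \in [0, 1]$: 0 means strictly additive, 1 means the
architecture deviates from additivity as much as those frequencies allow.

Both $\sigma^2_H = \beta' A \beta$ (with $A = 2(\mathrm{diag}\,\pi -
\pi\pi')$) and $\sigma^2_G = \beta' S \beta$ (the projection operator of
the additive design) are quadratic forms in $\beta$, so $\tau$ is a
generalized Rayleigh quotient. `tau_max()` therefore solves the problem in
closed form: whitening by $A$ restricted to its range turns
$\tau_{\max}$ into $1 - \lambda_{\min}$ of the whitened captured-variance
operator, with the minimizing eigenvector as the maximally non-additive
effect vector $\beta^\ast$. This is deterministic and exact, which we
prefer to a multi-start numeric ascent: the test suite checks it dominates
a dense random search over effect directions.

A structural point that the implementation makes explicit: a non-additive
haplotype effect generally contains a *pure-phase* component — contrasts
between diplotypes that share the same unphased genotype (for two SNPs,
the $\{00,11\}$ versus $\{01,10\}$ resolution of the double
heterozygote). No design computed from unphased genotypes, not even the
saturated genotypic one, can capture that component: the population
ceiling for every such design is $\operatorname{Var}(E[Y \mid G])$.
Consequently, along the canonical path the additive capture decreases
with $\tau'$ while the genotypic and haplotype-probability captures stay
strictly between the additive capture and $\sigma^2_H$. (In finite
samples their *raw* in-sample estimates sit above the ceiling by roughly
$\mathrm{df}_1/n$, which at $3^m$-class designs is large enough to make
the raw curves look flat near $\sigma^2_H$; the adjusted estimates show
the true ceiling.) `tau_max(identifiable = TRUE)` restricts the
maximization to phase-identifiable effects instead; for haplotype-linear
traits over two SNPs that subspace collapses onto the additive span, which
is why the unconstrained maximizer is the canonical one.

`effect_path()` produces effect vectors at any requested $(\sigma^2_H,
\tau')$: it interpolates between a strictly additive endpoint (the
$A$-projection of $\beta^\ast$ onto the span of $H$'s columns, i.e. per-
allele effects) and $\beta^\ast$, both normalized to unit haplotype
variance and sign-aligned so the path never collapses, rescales to the
target variance, and solves the interpolation weight by root bisection on
the recomputed $\tau'$. Any monotone path between the endpoints would
serve; the self-consistency property $\tau'(\text{path}(t)) = t$ (checked
to $10^{-6}$) is the contract, not a specific $\beta$.

## Power

For the regression models, under a population variance proportion $R^2$
the joint $F$-statistic is non-central $F(\mathrm{df}_1, \mathrm{df}_2)$
with non-centrality $nR^2/(1-R^2)$ (`analytic_power_f()`). We implement
the quotient form: a product form $nR^2(1-R^2)$ is dimensionally
inconsistent with the classical fixed-score non-centrality and disagrees
with simulation, while the quotient matches empirical power within Monte-
Carlo error (this equivalence is an acceptance-level test). For the
variance-component test, power is computed by the same weighted-
chi-square machinery: under $\operatorname{Var}(y) = \sigma^2_g\Gamma +
\sigma^2_e I$ the quadratic form has weights $\lambda_i(\sigma^2_g
\lambda_i + \sigma^2_e)$, and `analytic_power_vc()` compares the
alternative tail with the null critical value.

## The simulation engine

`scenario_config()` bundles a generative system, sample size, replicate
count, masked SNPs, models and $\alpha$; `run_scenario()` spawns one
derived seed per replicate (so results do not depend on evaluation order),
draws diplotypes, standardizes the trait, fits every requested model on
the observed (unmasked) genotypes and aggregates means, Monte-Carlo SEs
and empirical power.

**Nuisance SNPs.** `extend_with_nuisance()` appends zero-effect SNPs at a
target pairwise $r^2$ with every other SNP. For $r^2 = 0$ the product
measure is exact; otherwise the joint haplotype frequencies are found by
penalized least squares on the squared-correlation targets over the
frequency simplex (softmax parametrization, BFGS, multiple starts), with
the causal sub-distribution constrained to stay fixed. Residual deviations
above $10^{-6}$ raise an error naming the worst pair rather than silently
approximating — some $(\xi, r^2)$ combinations are geometrically
infeasible.

**Rare-variant tagging.** `rare_tagging_scenario()` reconstructs the
tagging geometry from its defining constraints: a rare allele (frequency
$f$, default $(1/24)^2 \approx 0.0017$) resides exclusively on the 1–1
haplotype of two common SNPs in mutual linkage equilibrium, so the
tagging haplotype has $D' = 1$ and $r^2_{\text{hap}}$ with the rare
allele; the 1–1 haplotype frequency is $h = f/(r^2_{\text{hap}}(1-f)+f)$
and each common SNP has frequency $\sqrt h$, which puts the per-SNP $r^2$
with the rare allele at $p/(1+p) = 0.04$ for $p = 1/24$ — inside the
0.03–0.05 band such designs aim for. The rare effect is sized so
$2f(1-f)\beta^2$ equals the requested variance. A structural observation
worth recording: at $r^2_{\text{hap}} = 1$ the ambiguous double-
heterozygote class receives *equal* posterior mass from the $\{01,10\}$
and $\{00,11\}$ phasings for any $p$, so roughly half of the tagging-
haplotype signal is irreducibly lost to phase ambiguity; the exact
population capture of the haplotype-probability design here is 0.0054 of
the 0.01 generated. The in-sample estimate sits above that (finite-sample
fitting of a rare dosage), which is the quantity a simulation study
reports.

**Panels.** `generate_fixture_panel()` emulates a phased reference panel
with a latent Gaussian AR(1) threshold process: adjacent-SNP latent
correlation $e^{-d/L}$ gives monotonically decaying LD with distance, and
per-SNP thresholds give an exact target MAF spectrum. It deliberately does
*not* model recombination hotspots, mutation age, rare-haplotype sharing
or population structure — so passing tests on these panels demonstrate
correct behavior under realistic LD decay, not robustness to every
feature of real data. `panel_window_scenario()` applies the MAF $> 0.01$
filter and greedy $r^2 \le 0.8$ pruning, takes a window, designates an
adjacent causal pair, and builds its effects with `effect_path()` from the
pair's empirical haplotype frequencies.

## The empirical pipeline

`prepare_phenotype()` log2-transforms (optionally), removes samples
outside the 1st–99th percentile range (trimming matches the removal
semantics; clamping is available behind a flag), residualizes jointly on
covariates and all candidate-SNP dosages at once, and standardizes.
`ld_prune()` is the classic greedy windowed pruning (window 100, step 50,
$r^2 = 0.8$ by default; the earlier-position SNP is kept on ties).
`make_windows()` builds per-chromosome sliding windows (size 100, step
50 by default), dropping trailing partial windows — a chromosome with $m$
SNPs yields $\lfloor (m - \text{size})/\text{step} \rfloor + 1$ windows,
which is why a genome-wide window count is smaller than the naive
single-pool count. `scan_windows()` fits the additive model per window;
`centered_scan()` slides windows away from candidate SNPs one SNP at a
time and reports the genomic-distance summaries (median center distance;
median minimal boundary distance, 0 when the candidate lies inside the
span).

**Variance explained** (`permutation_adjusted_total()`): per-window
in-sample $R^2$ is computed on the real phenotype and on `n_perm`
phenotype permutations (which preserve the genotype LD structure); the
adjusted contribution of a window is real minus permutation-mean, and the
total is their sum over windows, assuming additive contributions —
overlapping windows are detected and reported. The p-value is one-sided
(excess variance) with the +1 convention; the 95% CI adds the 2.5/97.5
percentiles of the window-wise centered permutation totals to the
observed total (a normal-approximation CI is available behind a flag).
The permutation-mean centering is applied before counting permutation
totals — the convention we fixed where the procedure's description is
ambiguous. Negative adjusted totals are legitimate outputs. A known
limitation, deliberately accepted: the CI reflects null variability only,
so under a strong genuine signal it slightly under-covers (the
signal–noise cross-term $4R^2(1-R^2)/n$ of the real-phenotype $R^2$ has
no permutation counterpart); with 100-SNP windows the null
width dominates and empirical coverage in our parameter-recovery tests is
at or above 90%.

**Enrichment** (`roc_auc()`, `enrichment_or()`, `offset_enrichment()`):
windows encompassing a candidate position (inclusive bp span) are
positives; the AUC uses midranks with the tie-corrected Mann–Whitney
normal approximation, one-sided for enrichment — the direction in which
such analyses are read. The odds ratio is the 2×2 cross-product with a
Woolf CI and Fisher exact p, Haldane-corrected (and flagged) when a cell
is empty. Per-offset enrichment reports the largest offset up to which
*every* offset has a significant AUC, together with that offset's distance
summaries.

## Reproducing study-scale numbers

The simulation defaults are the study conditions: $n = 5000$ individuals,
10000 replicates, $\alpha = 5\times10^{-5}$ for suggestive regional
association, haplotype variance 0.006 for the common-variant scenarios,
rare-variant variance grid $\{0.0025, 0.005, 0.01, 0.02\}$. The bundled
acceptance script (`scripts/acceptance.R`) and the acceptance-level tests
run 5000 replicates — the Monte-Carlo SE of a mean variance estimate at
5000 replicates is already below $5\times10^{-5}$, an order of magnitude
tighter than the effects being measured — and the calibration tests use
$n = 300$–500 with $10^4$ null replicates, sizes chosen so the whole
suite stays comfortably reproducible on a single CPU. The permutation
parameter-recovery experiment runs 50 repeats of 20 candidate windows of
100 SNPs at $n = 3740$ with 150 permutations.

## Known limitations

* No REML/GCTA-style mixed-model variance components, and no relatedness
  handling: all individuals are assumed unrelated.
* The genotypic and haplotype-probability designs grow as $3^m$ and are
  refused beyond `genotypic_max` (default 8) and `max_snps` (default 12)
  SNPs respectively.
* The panel generator produces realistic LD decay but not coalescent
  genealogy; rare-variant sharing patterns in real panels are richer.
* Untyped rare variants are only partially recoverable by any of the
  models — that gap is quantified, not solved, here.
* Closed-form (non-permutation) estimators of regional variance explained
  under LD are out of scope.
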