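---
title: "Protecting polygenic score association tests from stratification bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protecting polygenic score association tests from stratification bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataxis)
```

## The problem

A polygenic score is a weighted sum of genotype dosages,
$\hat Z_i = \sum_\ell \hat\beta_\ell X_{i\ell}$, with weights estimated in a
GWAS panel of $M$ individuals and applied in a separate test panel of $N$
individuals. A common downstream analysis regresses the scores on a
standardized *test vector* $T$ observed in the test panel — latitude, deme
membership, a genetic principal component — and asks whether the slope

$$\hat q = \tfrac{1}{N}\hat Z^\top T$$

differs from zero. Under a neutral null the true $q$ built from the causal
effects has expectation zero. But the estimated effects absorb any
correlation between ancestry and environment in the GWAS panel, and if the
two panels share population structure those per-site biases line up with the
genotype contrasts of the test, $r_\ell = \tfrac{1}{N}X_\ell^\top T$, and
accumulate: since $\hat q = \hat\beta^\top r$ over the score sites, a small
per-site bias becomes an $S$-fold bias of the test statistic.

The central object is the single axis of GWAS-panel structure that matters
for a *given* test: the cross-panel relatedness projected through the test
vector, $\tilde F_{Gr} = \tilde F_{GX} T$. Confounders orthogonal to this
axis cannot bias the test, and controlling for this one axis as a GWAS
covariate is sufficient to protect it — no matter what the confounder looks
like. The package provides:

* a **direct estimator** of that axis from the test-panel genotype
  contrasts, $\hat F_{Gr,i} = \tfrac{1}{L}\sum_\ell \tilde g_{i\ell}
  r_\ell / v_\ell$ (`direct_estimator_FGr()`), where $\tilde g$ are
  GWAS-centered dosages and $v_\ell$ the GWAS genotype variance;
* the standard **sample-PC correction** (`sample_pcs()`) together with the
  random-matrix theory for how well a sample PC can track a population PC
  (`pc_accuracy_theory()`);
* simulators, association machinery and error estimators to study when each
  correction works.

## Demographic simulators

Both simulators generate *independent biallelic sites* — the study design
deliberately excludes linkage — so genotypes can be simulated at the level
of population allele frequencies:

1. an ancestral frequency $a_\ell$ is drawn from a $1/x$ spectrum on
   $(0.005, 0.995)$ (the neutral segregating-site shape; only the shape near
   the MAF filter boundary matters downstream, because every headline
   statistic is an $a(1-a)$-weighted ratio of averages);
2. frequencies drift along the demography;
3. diploid dosages are binomial draws given the leaf frequency, and a joint
   MAF filter keeps sites with minor allele frequency at least 0.01 in
   *both* panels (3x surplus simulation with one retry).

For **tree demographies** (`tree_demography()`, `simulate_tree_panels()`)
each branch applies a Balding–Nichols (Beta) transition with
$F = 1 - e^{-t/(2N_e)}$, which has exactly the drift mean and variance, so
compounded branches reproduce the diffusion expectation for any split
configuration. The two-split tree with $N_e = 10{,}000$ and splits at
200/100 generations gives average Hudson $F_{ST}$ of about 0.01 and 0.005
between populations separated by the deep and shallow splits, and a single
12-generation split gives about 0.0006; the test suite checks these against
the closed form $1-e^{-t/2N_e}$ and against an explicit forward
Wright–Fisher oracle.

For the **stepping-stone grid** (`grid_demography()`,
`simulate_grid_panels()`) structure extends infinitely far back, so deme
frequencies are drawn from the migration–drift equilibrium of the linearized
recursion $\delta' = WA\delta + \varepsilon$, where $A$ is the migration
matrix, $W$ removes the grand mean (absorbed into $a_\ell$), and
$\mathrm{Var}(\varepsilon_d) = (1 - C_{dd})/2N_d$. The equilibrium
covariance solves a discrete Lyapunov equation by fixed-point iteration
(cached per demography). Defaults follow the study conditions: a 6×6
lattice, symmetric migration $m = 0.01$, deme size 1,000, 80 sampled
diploids per deme split evenly between panels ($M = N = 1{,}440$).

What the simulators do *not* emulate: linkage disequilibrium (real-data
users must LD-prune), selection at causal loci (drift-only nulls), mutation
recurrence, uncertainty in genotype calls, and any non-equilibrium
demography on the grid. Passing tests therefore speak to the statistical
behaviour of the estimators under clean independent-site structure, not to
robustness against LD or call-rate artefacts.

## Phenotype model

`environmental_phenotype()` draws $y_i \sim N(0,1) + c_i$ where $c$ encodes
the confounder: a mean shift $\Delta_{AB}$ for GWAS population B, a
latitudinal gradient $c = (\text{row}-1)\Delta/5$ (maximum shift exactly
$\Delta$; rows are indexed from 1, so the printed increments-by-row rule is
anchored at zero), a diagonal gradient $c = \tfrac{\text{row}+\text{col}}{2}
\Delta/5$ (with a `diagonal_demes_only` switch that shifts only the demes on
the diagonal — the gradient reading is the default because the bias only
depends on contrasts of $c$ with genotypes, and a smooth gradient is the
natural spatial confounder), or a single-deme shift at deme (1,4).

`heritable_phenotype()` adds an architecture: `n_causal` sites drawn
uniformly, effects $\beta_\ell \sim N(0, \sigma_i^2 [p_\ell(1-p_\ell)]^
\alpha)$ with $\alpha = -0.4$ by default, and $\sigma_i^2$ solved exactly so
the genetic variance equals the target $h^2$ (0.3 by default). A true
association of tunable strength is planted by aligning $\mathrm{sign}
(\beta_\ell)$ with the test-panel frequency difference $p_D - p_C$ with
probability $\theta \in [0.5, 1]$.

## The bias formula and a factor of two

For a purely environmental confounder of size $\Delta_{AB}$, the per-site
effect estimate decomposes exactly (the test suite asserts this to
$10^{-10}$) as

$$\hat\beta_\ell = \frac{\Delta_{AB}}{2}\,
\frac{\hat p_{B,\ell} - \hat p_{A,\ell}}{v_\ell} +
\frac{G_\ell^\top \varepsilon}{G_\ell^\top G_\ell},$$

the $1/2$ converting a between-group mean shift into a per-allele slope.
With $S$ score sites the expected bias of $\hat q$ is therefore

$$E[\hat q - q] = \frac{\Delta_{AB}\, S}{2}\,\tilde F_4(A,B;C,D),$$

where `f4_standardized()` keeps Patterson's convention,
$\tilde F_4 = \tfrac{1}{L}\sum_\ell (\hat p_A - \hat p_B)(\hat p_C - \hat
p_D)/v_\ell$, and `predicted_bias()` carries the $1/2$. Two practical
caveats, both verified in simulation:

* the equality holds when the $S$ score sites are chosen independently of
  their association signal. Ascertaining by minimum p-value inflates the
  realized bias by the selection factor $E[t^2 \mid \text{ascertained}] /
  E[t^2]$ — roughly six-fold at $S/L = 300/4000$ with $M = 1{,}000$ —
  because selection favours sites whose noise aligns with their drift. The
  experiment driver therefore exposes `ascertainment = "random"` for
  validating the formula and `"pvalue"` (the default, matching real
  pipelines) for everything else;
* $\tilde F_4$ is measured on the same simulated panels as the GWAS, so the
  prediction and the measurement share the realized drift.

## Controlling the test

`marginal_gwas()` fits, per site, OLS of the phenotype on (intercept,
dosage, covariates) via Frisch–Waugh–Lovell residualization — numerically
identical to the per-site joint fit (checked against `lm()` to $10^{-8}$) —
with $t$ p-values on $M - 2 - k$ degrees of freedom and dosages on the
allele-count scale. Covariates are standardized structure axes: the true
axis (tree models, `true_structure_axis()`), the direct estimator, or top
sample PCs. The within-GWAS-panel behaviour that protects the test is that
the fitted effects become uncorrelated with the genotype contrasts under the
null.

Sample PCs are computed from the column-centered, variance-standardized
dosage matrix with eigenvalues on the scale where a structureless panel has
bulk mean 1, so the detection threshold $1 + \sqrt{M/L}$ and the accuracy
formula

$$(U^\top\hat U)^2 \approx
\frac{1 - (M/L)/(\lambda-1)^2}{1 + (M/L)/(\lambda-1)}$$

apply directly; both branches are reproduced empirically by the test suite
within ±0.1. Eigenvector sign is fixed first-nonzero-positive, and all
axis comparisons use squared correlations, so sign conventions never affect
results. PCs and $\hat F_{Gr}$ are always computed on the same joint-MAF
SNP set.

## Quantifying estimator error

Where the true axis is known (tree models), `axis_error()` reports
$1 - \mathrm{cor}^2$. On the grid the truth is unknown, but individuals
within a deme are exchangeable, so `grid_error_direct()` attributes to error
the within-deme variance plus the across-replicate variance of deme means,
over the total variance; `grid_error_pc_bound()` reports only the
within-deme component for PCs (rank matching across replicates is not
well-defined), a lower bound that is tight in practice because the
within-deme term dominates. Both estimators are validated against
hand-computed examples and against synthetic data with a planted
signal-to-noise split.

## Numerical and design choices

* **Degenerate axes.** The true test-relevant axis of the unconfounded tree
  is constant (no axis needs protecting); such axes are flagged and
  contribute no covariate rather than erroring mid-experiment.
* **Ties and determinism.** Ascertainment breaks p-value ties by ascending
  site index; every experiment derives one seed per replicate from the
  master seed (`derive_seed()`), so replicates can run in any order and a
  config plus master seed reproduces every table exactly.
* **Genotype variance denominators.** Empirical mean squared centered
  dosage by default; an expected-variance $2p(1-p)$ option exists but is
  off by default.
* **F_ST.** Hudson's estimator with the $\hat p(1-\hat p)/(n_{chrom}-1)$
  correction, combined across sites as a ratio of averages; this is the
  estimator whose drift expectation matches the reference values above.
* **Monomorphic/collinear sites** are flagged `NA` and excluded from
  ascertainment rather than imputed; monomorphic sites should not survive
  the joint MAF filter in the first place.
* **Scaling sweeps.** For comparisons across $L$ the score size is held
  proportional ($S = 0.05L$ tree, $S = 0.015L$ grid presets) so the
  expected bias stays comparable across the sweep.

## Problem sizes

The `"full"` presets of the experiment configs carry the full study
conditions (tree: $M = N = 10{,}000$, $L = 10{,}000$, $S = 300$, 100
replicates; grid: $M = N = 1{,}440$, $L = 20{,}000$, 100 replicates; error
sweeps to $L = 100{,}000$). The test suite and examples run the `"smoke"`
presets and reduced sizes chosen so every qualitative contrast is decisively
powered at a fixed seed: e.g. the single-deme grid check uses 40 sampled
diploids per deme, $L = 8{,}000$, $\Delta = 0.6$ and 20 replicates — the
confounder is scaled up so that "ten PCs stay biased while the direct
estimator protects the test" is a statistically decisive contrast at that
replicate count, while the latitude scenario keeps the reference
$\Delta = 0.2$. Full-preset runs reproduce the reference error values
(e.g. direct-estimator latitude error near 0.012 at $L = 20{,}000$; the
two reported figures 0.012 and 0.011 for that quantity differ only by
rounding) but take hours on one CPU and are not part of the test suite.

## Known limitations

* Marginal effects only: no joint or mixed-model estimation, no LD-aware
  methods; with linked sites, jointly estimated effects would dilute (not
  remove) stratification bias.
* The iid test statistic: no GLS accounting for relatedness among test
  panel individuals, so `q_hat` comes without a calibrated standard error
  for single data sets — inference in the package is replicate-based.
* Real-data input must be complete (no missing genotypes) and pre-pruned;
  `read_vcf()` refuses missing or multi-allelic records.
* The grid equilibrium is a linearized Gaussian approximation; frequencies
  are clipped to $[0,1]$, which very slightly compresses extreme
  frequencies at high ancestral MAF. Differentiation magnitudes used here
  (per-site $F_{ST}$ of a few percent) are well inside its accuracy range.
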