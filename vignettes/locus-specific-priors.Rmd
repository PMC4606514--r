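---
title: "Locus-specific mixture priors for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-specific mixture priors for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesbpi)
```

## The problem

Genomic selection predicts the additive genetic merit (GEBV) of candidates
from genome-wide SNP genotypes, using a reference population that is both
genotyped and phenotyped. The Bayesian "alphabet" methods assume most
markers have no effect: BayesB places a point mass at zero on each marker's
effect variance with prior probability π and a scaled inverse-χ² slab
otherwise, with π fixed at a constant such as 0.95 for every marker. That
constant ignores what is often known — or cheaply estimable — about a
trait's genetic architecture: a trait governed by a major gene (milk fat
percentage with *DGAT1* is the canonical dairy example, the gene accounting
for roughly 30% of the genetic variance) concentrates its signal in a few
genomic regions, while a purely polygenic trait such as somatic cell score
does not.

BayesB-π makes π a *vector*. A single-marker ANOVA of the training data
gives per-marker p-values; on the evidence scale ω = −log₁₀(p), the prior
probability that marker *i* is non-effective is the min–max rescale

π*ᵢ* = (max(ω) − ωᵢ) / (max(ω) − min(ω)).

The most associated marker gets π = 0 (its variance is proposed every MH
cycle), the least associated π = 1 (never proposed). Everything else about
the BayesB sampler is unchanged, which makes the comparison between constant
and locus-specific priors clean.

## Models and samplers

**GBLUP.** `y = 1μ + u + e`, `u ~ N(0, σ²_u G)`, with the VanRaden (method
1) relationship matrix `G = WW′/(2Σ pⱼ(1−pⱼ))`, `W` the genotype matrix
centered by twice the allele frequency. Variance components are estimated
by REML: one eigendecomposition of `G` reduces the restricted likelihood to
a function of the single ratio δ = σ²_e/σ²_u, maximised by Brent
optimisation of log δ on `[-12, 12]`. Predictions for unphenotyped
individuals propagate through the corresponding blocks of `G`; since
genotypes carry no phenotype information, `G` is built from training and
validation individuals together, the standard practice in cross-validation.
The implementation is checked against an independent oracle: with matched
penalty λ_marker = λ_G · 2Σpⱼqⱼ, GBLUP GEBVs must equal centered-genotype
ridge-regression predictions to 1e-6.

**BayesA / BayesB / BayesB-π.** The marker model is
`y = Xb + Σ zᵢgᵢ + e` with `b` reduced to an overall mean. One sweep of the
Gibbs sampler updates, per locus, the effect variance and the effect, then
the residual variance from x⁻²(n − 2, e′e) and the mean from
N((1′y − 1′Wg)/n, σ²_e/n). BayesA draws each variance from its conjugate
full conditional x⁻²(ν + 1, S + g²). BayesB and BayesB-π instead run an
inner Metropolis–Hastings loop: each cycle draws α ~ U(0,1); if
α < 1 − πᵢ the proposal is a slab draw S/χ²_ν, otherwise the point mass at
0. Because the proposal is the mixture prior itself, the acceptance
probability reduces to the likelihood ratio, where the likelihood is the
*marginal* likelihood of the locus-adjusted data with the effect integrated
out, `y_adj ~ N(0, σ² w w′ + σ²_e I)`, evaluated in O(1) per cycle via the
rank-one determinant and Sherman–Morrison identities (unit-tested against a
dense-covariance evaluation). After the cycles, a positive variance leads
to a conjugate normal effect draw; a zero variance drops the locus.

The published description of the closed gate ("the variance is not
resampled and set as 0 or not updated according to the likelihood ratio")
admits two readings. The default here still subjects the zero proposal to
the accept/reject step; a strict mode (`strict_gate = TRUE`) skips the
cycle entirely. On simulated data the two are practically
indistinguishable; both are exposed for sensitivity analysis.

**Defaults.** ν = 4.234 and S = 0.0429 for the marker-variance slab,
residual prior x⁻²(−2, 0) (flat on the variance), π = 0.95 for BayesB,
10,000 sweeps with 2,000 burn-in and 100 MH cycles. S is used as-is for
standardized phenotypes; it is not rescaled by trait variance. At desk
scale, 5–10 MH cycles and a few thousand sweeps give posterior means
indistinguishable from the full protocol, and the tests use such reduced
settings (sizes below).

**Reproducibility.** The chain is driven by a counter-based generator keyed
by (seed, sweep, locus), so results are bit-reproducible across platforms
and — because loci are visited in key order — invariant to permuting
markers together with their keys and priors. Initial values follow the
small-positive-numbers convention (μ = g = 0.01, σ²_g = 0.01,
σ²_e = var(y)/2). Genotype columns are centered by 2pⱼ (training
frequencies) before sampling; a raw-coding mode exists for exact
replication of the uncentered model, changing only the interpretation of μ.

## The locus prior in practice

`single_marker_anova()` treats the genotype classes (0/1/2) as factor
levels — the class-means reading of "ANOVA on single markers" — and is
vectorised over markers by group-sum identities; an additive-dosage
regression F-test is available and nearly identical for common variants.
The default fixed-effect design is intercept-only. There is no kinship or
principal-component correction and no multiple-testing adjustment: the π
transform consumes raw p-values by construction.

Numerical choices:

* p-values are floored at 1e-300 so ω stays finite;
* monomorphic markers carry an undefined sentinel (`NA`), mapped to ω = 0,
  i.e. treated as maximally non-significant (π = 1 after rescaling);
* ties at max(ω) all receive π = 0, a direct consequence of the formula;
* if every ω is equal the rescale is undefined and the package falls back
  to a constant π = 0.95 with a warning — the trait is then effectively
  architecture-free and BayesB-π degenerates to BayesB, which is the
  sensible limit.

One known sensitivity: the denominator max(ω) − min(ω) is set by the single
most significant marker, so the absolute π scale varies between traits
(major-gene traits spread π further down from 1 than polygenic ones). A
binned variant (`compute_locus_pi_binned()`) assigns one π per p-value
class to damp this; it is off by default because it introduces thresholds
that would need trait-specific care.

In cross-validation the prior is recomputed inside every training fold
(`pi_mode = "per_fold"`), so validation responses can never leak into the
prior; a deliberately leaky `"full_data"` mode exists only to probe how
much that matters. Whether a full-data analysis should compute π once or
per fold is genuinely open; per-fold is the defensible default and the
tests assert the no-leakage property by recomputation.

## What the simulator emulates — and what it does not

`arch_spec()` / `simulate_dataset()` generate genotypes in Hardy–Weinberg
proportions with allele frequencies uniform on an interval (default
0.05–0.5) and, by default, linkage equilibrium between markers. Effects are
Gaussian for background QTL; one designated major locus can be sized so its
variance contribution 2pqa² is an exact fraction of the total genetic
variance at the realized frequencies. Phenotypes add Gaussian noise tuned
to a target heritability.

Three presets mirror the contrasting dairy-trait architectures discussed in
the genomic-prediction literature, and their parameters were fixed once, as
the study conditions for all tests:

* `mfp_like` — 50 QTL, one major locus at 30% of genetic variance,
  h² = 0.5 (the *DGAT1*-like case);
* `my_like` — 100 QTL, a moderate lead locus at 10%, h² = 0.5;
* `scs_like` — 200 exchangeable small QTL, no designated major locus,
  h² = 0.30 (a low-heritability, purely polygenic trait).

Linkage equilibrium is a deliberate simplification: it makes the ANOVA
p-value behaviour analytically predictable (exact type-I error, a clean
mapping from the major QTL to the minimum p-value), which is what the tests
need. Real SNP panels have extensive LD, so on real data the ω profile is
smeared across neighbouring markers and π is locally correlated; an
optional block-equicorrelated mode (`ld = list(block_size =, rho =)`)
provides a first-order approximation of that. The simulator has no
pedigree structure, no selection, no minor-allele-frequency spectrum from
real chips, and no non-additive effects — so passing tests demonstrate
correctness of the machinery and the *direction* of architecture effects,
not the absolute accuracies attainable on any real population.

## The validation protocol

`make_cv_plan()` optionally draws a random subpopulation (the size ladder
200/500/1000/2000 is the classical design), then partitions it into k
balanced folds per repeat; 5-fold × 20 repeats and 10-fold × 10 repeats
both yield 100 validation sets. Accuracy is the Pearson correlation between
GEBVs and held-out responses; unbiasedness is an OLS slope. The protocol's
literal wording regresses *GEBVs on responses*, which disagrees with the
field's convention (responses on GEBVs, slope 1 = calibrated); both are
recorded, the literal one as the default `unbiasedness` column. Standard
errors are SD/√(number of validation sets); size-ladder summaries add a
"Mean" row that averages the per-size means (not pooled fold records), and
a best-method flag per row group. Method failures inside a fold are flagged
and aggregation continues on the remaining folds with a warning.

## Problem sizes used by the tests and acceptance script

All heavier checks run on simulated data at sizes chosen to make sampling
noise manageable while keeping a desk-scale footprint: parameter recovery
and method contrasts use n = 500 (training ≈ 400 per fold) with m = 1000
markers, chains of 1000–2000 sweeps with 5–10 MH cycles; the polygenic
contrast uses n = 300; the ANOVA calibration uses 1000 null markers at
n = 200; REML recovery uses n = 1000, m = 2000. The acceptance script runs
the full cross-validation pipeline at these sizes from a single `--seed`.

## Limitations

* Effects are single-SNP; haplotype-segment variants of the same machinery
  are out of scope (`n_i` in the variance update is fixed at 1).
* π is an input, never sampled: BayesCπ/BayesDπ-style estimation of π from
  the data is intentionally not implemented.
* The ANOVA scan is marginal; in strong LD the locus prior rewards entire
  regions, and the method inherits whatever confounding (e.g. structure)
  the scan has.
* REML uses a dense eigendecomposition, adequate to a few thousand
  individuals; no sparse or APY-style approximations are provided.
* Missing genotypes are mean-imputed only; no phasing or LD-based
  imputation.
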