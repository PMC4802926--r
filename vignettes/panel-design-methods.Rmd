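---
title: "Methods: characterising and designing structured association panels"
author: "assocPanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterising and designing structured association panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genome-wide association studies in perennial crops start from a germplasm
collection of thousands of clonally maintained cultivars. Such collections
are structured (distinct gene pools), full of close relatives (parent-
offspring chains of named cultivars), and far too large to phenotype. An
association panel is a subsample designed to (i) represent the collection's
allelic and phenotypic diversity, (ii) balance the main genetic subgroups,
and (iii) carry as little first-degree relatedness as possible, because
structure and kinship are confounders for both linkage disequilibrium (LD)
and association tests. `assocPanel` implements the quantitative toolkit for
this workflow: diversity description, marker-based coancestry, kinship- and
structure-corrected LD, LD-decay modelling, multiple-testing correction,
analytic mixed-model power, the panel-design algorithm itself, and a
ground-truthed synthetic generator used to validate everything end to end.

# Data model

`GenotypePanel` holds diploid genotypes of two marker classes: biallelic
SNPs as additive dosages with heterozygotes at 0.5 (0 and 1 the two
homozygotes) -- the coding the association mixed model uses directly as its
regressor -- and multiallelic SSR loci as unordered integer allele pairs.
The locus map is 1-based bp positions; distances are `|pos_i - pos_j|`;
genotypes are site-level so strand and phase play no role. A
`StructureMatrix` holds membership coefficients (rows on the probability
simplex) from any model-based clustering; the package treats it as an
input, not something it estimates.

# Diversity and differentiation

Per locus and group: allele count Na, effective allele number
`Ne = 1/sum(p_i^2)`, expected heterozygosity `He = 1 - sum(p_i^2)` (no
small-sample correction, so `Ne = 1/(1-He)` exactly), observed
heterozygosity, minor allele frequency (for multiallelic loci: the
frequency of the second most common allele, which is always at most 0.5),
and Nei's index (= He). Pairwise differentiation is Weir & Cockerham's
theta with ratio-of-sums combination over loci and alleles; negative
estimates are reported as computed. The estimator choice is a documented
interpretation: the source workflow names only a software tool, and theta
is the standard, testable variant.

# Coancestry estimators

Five marker-based estimators, one interface:

* **AIS** -- alikeness in state: the probability that one allele drawn from
  each individual matches, `1/4 [I(a=c)+I(a=d)+I(b=c)+I(b=d)]`, averaged
  over shared loci. Always in [0,1]; as a Gram matrix of allele fractions
  it is positive semi-definite. Its diagonal is `1 - Ho(i)/2`.
* **WAIS** -- AIS corrected per locus by `s_l`, the mean AIS over pairs of
  individuals from groups assumed unrelated: `(AIS_l - s_l)/(1 - s_l)`,
  averaged over loci. With two or four assumed-unrelated groups the tag is
  WAIS2 or WAIS4. The per-locus versus global reading of the correction
  factors is an interpretation documented here: the original descriptions
  are one line each, and the per-locus form is the one that makes "two
  correction factors" (numerator and denominator per locus) meaningful.
* **BNO** -- the same correction with a single global factor `s` (mean AIS
  over all loci and cross-group pairs).
* **LOI** -- Loiselle's correlation-type estimator on individual allele
  frequencies, with the `sum_a p_a(1-p_a)/(n_l-1)` bias term that centres
  unrelated pairs at zero without assuming unrelated groups.
* **MLE** -- maximum-likelihood IBD coefficients `(k0, k1, k2)` per pair,
  maximising `prod_l sum_m k_m P(G_i, G_j | m)` with the classical
  two-genotype conditional probabilities; coancestry is `k1/4 + k2/2`. The
  weights are estimated by EM from `(1/3, 1/3, 1/3)` (at most 200
  iterations, log-likelihood tolerance 1e-6). Because the log-likelihood
  is concave in `k`, the only failure mode is slow geometric approach to a
  simplex vertex; a final vertex comparison therefore replaces the iterate
  whenever a vertex attains a higher likelihood. No genotyping-error
  parameter is included (the intended inputs are manually curated marker
  sets).

Corrected estimators legitimately go negative; the matrices retain those
values, and truncation at zero happens only where a matrix enters a model
covariance (whitening, mixed-model V).

**Which estimator to use?** True LD between loci on different chromosomes
is null, so whichever kinship correction drives mean inter-chromosomal
corrected LD closest to zero is removing the most confounding with the
least distortion. `selectEstimatorByInterchromLD()` implements exactly
that selection (ties broken in the fixed tag order). Two practical points
the package's own simulations make vivid: the kinship matrix should be
estimated from markers *disjoint* from the loci whose LD is being
corrected (estimating K from the same loci deflates their correlations and
makes raw AIS look spuriously good), and raw AIS -- whose entries sit
around 0.5-0.7 because IBS sharing includes non-IBD identity -- performs
poorly as a covariance for unlinked-locus LD, which is precisely why the
corrected estimators exist.

# Relationship classification

For pruning, pairs are classified by evaluating the pair log-likelihood at
the canonical IBD vectors U = (1,0,0), HS = (0.5,0.5,0), FS =
(0.25,0.5,0.25), PO = (0,1,0); the best category wins, ties preferring U
then HS, and an opposite-homozygote locus makes PO impossible (-Inf)
exactly as Mendelian inheritance requires. "First degree" means PO or FS.
Fixed-vector likelihoods rather than free MLE make the four hypotheses
directly comparable and the classifier deterministic.

# Corrected linkage disequilibrium

Classical `r2` is the squared Pearson correlation of dosages. The
corrected estimates generalise it to dependent samples: with kinship
covariance V (the truncated kinship matrix), both dosage vectors and the
covariates are whitened by the inverse lower Cholesky factor of V, the
whitened dosages are residualised on the whitened covariates, and the
corrected `r2` is the squared *uncentred* correlation of the residuals --
uncentred because the residuals are already orthogonal to the whitened
intercept, making the value exactly the generalised-least-squares
correlation `(x'Py)^2 / (x'Px)(y'Py)` with
`P = V^-1 - V^-1 1 (1'V^-1 1)^-1 1'V^-1`. `r2_V` uses the intercept only;
`r2_VS` adds the structure matrix columns (one dropped for
identifiability). Kinship enters as provided, with no doubling to a
relationship-matrix scale, and the same convention is used by the power
module so the two are mutually consistent.

Missing data are handled pairwise-complete, with K and S subset to the same
individuals; with complete dosages all loci are whitened once, which is the
fast path used on simulated panels.

**Positive definiteness.** Truncating a group-corrected estimator at zero
routinely leaves an indefinite matrix (cross-group blocks pinned at zero
against large within-group blocks; smallest eigenvalues near -0.3 on
simulated structured panels). The repair is: try Cholesky; retry once with
a ridge of `1e-6 * mean(diag)`; if still failing, clip eigenvalues from
below at 1% of the leading eigenvalue. The clip level bounds the whitening
condition number at 100: estimated near-null directions of a kinship
matrix are noise, and whitening must not amplify them by four orders of
magnitude (which demonstrably manufactures spurious corrected LD).

Sliding-window LD summarises a region: a window belongs to a pair only if
*both* loci lie inside it (the documented reading of the window
convention), windows step by a fixed amount from the span start, and
windows with fewer than the minimum pair count (default 10) report NA.

# LD decay, extent, and marker density

The expectation fitted to `r2` versus distance is the Hill-Weir
drift-recombination formula with first-order sample-size correction,

```
E[r2] = (10+C)/((2+C)(11+C)) * [1 + (3+C)(12+12C+C^2) / (n(2+C)(11+C))]
```

with `C = rho * d`. `n` is taken as the number of genotyped individuals
behind the LD table (a documented, configurable choice; the alternative
gamete count just rescales the small-sample term). The fit is unweighted
least squares in `rho` over [1e-12, 1] per bp with 8 log-spaced
multi-starts of a bounded quasi-Newton search on log(rho) --
multimodality is not expected but costs nothing to guard against -- and is
deterministic. LD *extent* is the distance where the fitted curve crosses
a threshold (0.2 by convention), solved by bisection to relative tolerance
1e-6. Marker densities derive from the extent at a target `r2`: with
markers every `2 d*`, no causal position is farther than `d*` from a
marker, giving `ceil(G / (2 d*))` markers for a genome of size G. The
factor-2 spacing convention is this package's documented choice; published
counts based on unstated conventions are not reproduced.

# Multiple testing and power

`meffLiJi()` computes the effective number of independent tests from the
eigenvalues of the locus correlation matrix,
`Meff = sum I(|l|>=1) + (|l| - floor|l|)`, and the per-test threshold is
`FWER / Meff` (plain division, not the Sidak form). Power uses the
standard association mixed model `Y = 1 mu + X_l beta_l + U + E` with
`U ~ N(0, K sigma2_gl)` and `E ~ N(0, I sigma2_e)` on a unit
total-variance scale: `sigma2_e = 1 - h2`, residual polygenic variance
`(1 - qEffect) h2`, and `beta_l` calibrated against the *empirical*
genotype variance (`beta^2 Var(x) = qEffect * h2`) so structured or
related panels need no Hardy-Weinberg assumption. Variance components are
treated as known; the Wald statistic for `beta_l` is then noncentral
chi-square with 1 df and noncentrality `beta^2 / var(beta_hat)`,
`var(beta_hat)` the locus entry of `(X'V^-1X)^-1`, and power is the upper
tail beyond the central chi-square quantile at alpha. The same
known-components model drives `empiricalPower()`, whose Wald rejection
rate is the Monte-Carlo check of the analytic value. Power at a marker
linked to the causal locus is the causal-locus power multiplied by the
corrected LD between them.

# Panel design

`designPanel()` follows the structure-first workflow: per subgroup, keep
individuals whose top membership reaches 0.8 (founder cultivars of the
subgroup are exempt -- they are retained by mandate); seed the selection
with the founders; fill to the target size greedily, always adding the
candidate whose minimum simple-matching dissimilarity to the current
selection is largest (a deterministic maximin stand-in for proprietary
maximum-length-subtree subsampling, with lexical tie-breaks); then
classify all within-panel pairs and, while any first-degree pair remains,
remove the non-founder member with the larger mean AIS kinship to the rest
of the panel, refill that subgroup by maximin, and repeat. Founders are
never removed; a first-degree pair of two founders is flagged and kept.
The loop terminates because every iteration permanently removes a
candidate or permanently accepts a founder pair. Representativeness of the
result is assessed by allele retention above a rare-allele threshold
(default MAF 0.05), the squared correlation of allele frequencies, and per
trait a Wilcoxon rank-sum mean test (normal approximation with tie
correction), a Brown-Forsythe variance test, and the captured-variance
ratio, with the panel compared against the full collection.

# The synthetic generator

`simulatePanel()` emulates the study conditions the analyses assume: three
cultivated subgroups plus a smaller wild group (90/92/90/62 individuals),
four ~2 Mb genomic regions carrying 372 SNPs in total, 129
genome-distributed SNPs, and 20 SSR loci. Subgroup allele frequencies
follow the Balding-Nichols Beta model around ancestral frequencies drawn
uniformly from [0.05, 0.5] (random minor side), with per-group F defaults
of 0.03/0.05/0.03/0.09 so pairwise differentiation lands in the 0.01-0.09
band (the realised pairwise value is approximately the mean of the two
groups' F). Within regions, LD comes from a haplotype-pool copying model:
each subgroup owns a small pool of founder haplotypes and every gamete
copies along the region, switching templates at a per-bp rate. Two sites
then correlate in proportion to the probability of sharing a template, so
`r2` decays from roughly `1/(H-1)` at zero distance (H the pool size)
towards the sampling background. The defaults (cultivated pools of 6,
wild 3, switch rate 5e-6/bp) put short-range `r2` near 0.2 and give the
wild group its expected lower diversity and longer LD; decay-extent tests
use a deliberately smaller pool (4) and rate 4e-6/bp, a configuration
calibrated once to an extent of about 50 kb at the 0.2 threshold.
Distributed SNPs and SSR alleles are drawn independently per individual --
no LD, and no pool-sampling drift -- which is why differentiation-recovery
checks target those loci: region loci carry extra drift from the finite
pools on top of the Balding-Nichols F. A copying model is used instead of
a coalescent because it is direct, fast, and gives tunable monotone decay,
which is all the analyses require.

`injectRelatives()` plants ground-truthed first-degree pairs:
parent-offspring (the child takes one recombination-free parental gamete
per region, random parental alleles at unlinked loci, and a fresh pool
gamete) and full sibs (two children of the same two freshly drawn
parents). `simulatePhenotype()` draws from the association mixed model
itself, so analytic power and empirical rejection rates are comparable by
construction. Everything flows from a single seed.

What the generator does *not* emulate: genotyping error and missingness
patterns of real assays, SSR mutation processes, admixed individuals
(membership is the generating indicator unless blurred), linked selection,
and any LD between regions. Passing tests therefore demonstrate estimator
correctness and internal consistency under the stated model, not
robustness to every artefact of real data.

# Problem sizes and numerical choices in the test-suite

The suite validates at the scale the methods are meant for while staying
quick: panels of 60-334 individuals, 129-521 loci, 500-locus
frequency-recovery checks, a 3x3 heritability-by-effect grid with 2000
phenotype replicates per cell at N = 270 for the power validation, 10
replicate simulations for the LD-direction and panel-design properties.
Determinism: every stochastic test fixes its generator seed; the decay
fit, maximin selection, and classifier are deterministic by construction.
Degenerate inputs are defined, not fatal: monomorphic loci give He = 0 and
Ne = 1, all-missing loci report NA frequencies, zero-variance loci are
dropped from Meff with a warning, and pairs sharing no genotyped locus get
NA kinship with a warning.

# Known limitations

* The WAIS/BNO correction-factor formulas follow one-line published
  descriptions; other readings (per group pair, per locus-and-group) are
  possible and would change corrected values, though not the centring
  property tests assert.
* The analytic power treats variance components as known; re-estimating
  them per phenotype would lower power slightly at small N.
* The maximin subsample is a greedy heuristic: it guarantees neither the
  optimal minimum pairwise distance nor the exact output of
  tree-based subsampling tools it replaces, only determinism and the
  random-baseline dominance the tests check.
* Meff from pairwise-complete correlations can be slightly biased with
  highly non-uniform missingness.
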