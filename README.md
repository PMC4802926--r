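# assocPanel

Tools for characterising germplasm diversity collections and designing
association (GWAS) panels from them, aimed at geneticists working with
structured, clonally maintained crop collections (grapevine-style
panels of a few hundred cultivars in a handful of gene pools, genotyped
at SSRs plus a few hundred SNPs).

Designing a GWAS panel from a large collection raises four linked
questions that this package answers quantitatively:

1. **How diverse and differentiated is the material?** Per-locus and
   per-group Na, Ne = 1/Σp², He = 1 − Σp², Ho, MAF, Nei's index, and
   pairwise Weir–Cockerham θ (ratio-of-sums over loci and alleles).
2. **Who is related to whom?** Five marker-based coancestry estimators —
   AIS (alikeness in state), its group-corrected forms WAIS (per-locus
   correction factor) and BNO (global factor), Loiselle's bias-corrected
   correlation estimator, and per-pair maximum-likelihood IBD
   coefficients (k₀,k₁,k₂) via EM, with coancestry k₁/4 + k₂/2 — plus a
   likelihood classifier of pair relationships (U/HS/FS/PO) used to
   detect first-degree pairs. The estimator used downstream is chosen by
   the package's own criterion: whichever kinship correction minimises
   mean corrected LD between loci on *different* chromosomes, where true
   LD is null.
3. **How far does linkage disequilibrium reach?** Classical r², and LD
   corrected for kinship (r²_V) or kinship and structure (r²_VS) by
   whitening with the inverse Cholesky factor of the kinship matrix and
   residualising on the (whitened) intercept and structure covariates —
   the generalised-least-squares correlation. Decay with distance is
   fitted with the Hill–Weir expectation
   E[r²] = (10+C)/((2+C)(11+C)) · [1 + (3+C)(12+12C+C²)/(n(2+C)(11+C))],
   C = ρd, giving the LD *extent* (distance where the curve crosses 0.2)
   and the genome-wide marker count needed to reach a target r² at the
   nearest marker.
4. **What can the panel detect?** Li–Ji effective number of independent
   tests (Meff) from the locus-correlation eigenvalues; analytic power of
   the Wald test under the association mixed model
   Y = 1μ + X_l β_l + U + E, U ~ N(0, Kσ²_gl), E ~ N(0, Iσ²_e), with
   known variance components and a noncentral-χ²(1) statistic; power at a
   linked marker as causal-locus power × r²_VS; and a Monte-Carlo
   validation that the analytic value matches the empirical Wald
   rejection rate.

The panel itself is designed by `designPanel()`: per subgroup, keep
individuals with membership ≥ 0.8, seed with mandatory founder cultivars,
fill by greedy maximin on simple-matching dissimilarity, then iteratively
remove first-degree relatives (classifier-flagged; the non-founder with
the larger mean kinship goes) and refill until clean.
`assessRepresentativeness()` scores the result by allele retention,
allele-frequency correlation, and per-trait rank-sum / Brown–Forsythe
tests. A ground-truthed synthetic generator (`simulatePanel()`,
Balding–Nichols differentiation, haplotype-pool copying LD, injected
PO/FS pairs, mixed-model phenotypes) underpins the test suite.

## Worked example

```r
library(assocPanel)

sim <- simulatePanel(simulationConfig(seed = 42))       # 3 cultivated + wild
sim <- injectRelatives(sim, poPerGroup = 2, fsPerGroup = 2)
gm  <- sim$panel
gm
#> GenotypePanel: 334 individuals, 521 loci (501 SNP, 20 SSR)
#>   subgroups: TE=90, WE=90, wild=62, WW=92
#>   overall missingness: 0.000

# kinship from the 149 genome-distributed markers (disjoint from the LD loci)
loc  <- locusInfo(gm); grp <- indInfo(gm)$subgroup
ksel <- loc$locus_id[loc$region %in% "distributed" | loc$locus_type == "ssr"]
K <- kinshipWAIS(gm[, ksel], grp)
K
#> KinshipMatrix (WAIS4): 334 individuals
#>   off-diagonal mean 0.0101, range [-0.3777, 0.3805]

# corrected LD decay inside one subgroup, over the four clustered regions
rsel <- loc$locus_id[grepl("^region", loc$region)]
we   <- which(grp == "WE")
Kwe  <- KinshipMatrix(as.matrix(K)[we, we], "WAIS4")
ld   <- pairwiseLD(gm[we, ], loci = rsel, K = Kwe)
fit  <- fitHillWeir(ld[!is.na(ld$dist_bp), ], n = length(we), ldColumn = "r2_v")
ldExtent(fit, 0.2) / 1000
#> LD extent at r2_V = 0.2: 17.9 Kb

# multiple testing and analytic power
gmr  <- filterLoci(gm[, rsel], minMaf = 0.05)
meff <- meffLiJi(gmr)                                    # 189 of 336 SNPs
x    <- snpDosage(gm)[, locusInfo(gmr)$locus_id[40]]
sp   <- powerSpec(h2 = 0.7, qEffect = 0.1, fwer = 0.05, meff = meff)
powerAtLocus(x, K, sp)                                   # 0.959
powerAtMarker(powerAtLocus(x, K, sp), 0.45)              # 0.431
```

Reading: in this synthetic panel the WAIS4 coancestry correctly centres
unrelated pairs near 0 (injected relatives sit at the top of the range);
within-subgroup corrected LD falls below 0.2 beyond ~18 Kb, so markers
every ~36 Kb would keep every causal locus above that LD with its nearest
marker; 336 region SNPs behave like 189 independent tests, and a locus
explaining 10 % of the genetic variance of a h² = 0.7 trait is detected
with probability 0.96 at the Meff-corrected threshold — dropping to 0.43
at a marker in r²_VS = 0.45 with the causal locus.

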