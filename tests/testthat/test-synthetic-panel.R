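test_that("the generator is deterministic under its seed", {
  a <- simulatePanel(simulationConfig(seed = 4))
  b <- simulatePanel(simulationConfig(seed = 4))
  expect_identical(snpDosage(a$panel), snpDosage(b$panel))
  expect_identical(ssrAlleles(a$panel), ssrAlleles(b$panel))
  expect_identical(as.matrix(a$Q), as.matrix(b$Q))
  c <- simulatePanel(simulationConfig(seed = 5))
  expect_false(identical(snpDosage(a$panel), snpDosage(c$panel)))
})

test_that("zero differentiation gives near-zero Fst at distributed loci", {
  cfg <- simulationConfig(
    seed = 6, groupSizes = c(g1 = 60L, g2 = 60L),
    fstTargets = c(g1 = 0, g2 = 0),
    regions = data.frame(chrom = character(), start_bp = integer(),
                         length_bp = integer(), n_snps = integer()),
    nDistributedSnps = 500L, nSsr = 0L,
    haplotypePoolSize = c(g1 = 6L, g2 = 6L))
  sim <- simulatePanel(cfg)
  expect_lt(abs(pairwiseFst(sim$panel)["g1", "g2"]), 0.01)
})

test_that("an infinite switch rate collapses LD to the independent-loci background", {
  cfg <- simulationConfig(
    seed = 8, groupSizes = c(P = 80L), fstTargets = c(P = 0.03),
    regions = data.frame(chrom = "chr1", start_bp = 1L,
                         length_bp = 1000000L, n_snps = 80L),
    nDistributedSnps = 0L, nSsr = 0L,
    haplotypePoolSize = c(P = 10L), switchRate = 1)
  sim <- simulatePanel(cfg)
  ld <- pairwiseLD(sim$panel, minMaf = 0.05)
  far <- ld$dist_bp >= 10000
  # independent-loci background oracle: same N, independent draws
  set.seed(80)
  Xi <- sapply(runif(80, 0.1, 0.9), function(p) rbinom(80, 2, p) / 2)
  bg <- mean(cor(Xi)[upper.tri(diag(80))]^2)
  expect_lt(abs(mean(ld$r2[far]) - bg), 0.01)
})

test_that("injected PO pairs obey Mendelian sharing and FS raise AIS", {
  sim <- simulatePanel(simulationConfig(seed = 12))
  sim2 <- injectRelatives(sim, poPerGroup = 3, fsPerGroup = 3)
  reg <- sim2$truth$registry
  expect_equal(nrow(reg), 18)
  po <- reg[reg$relationship == "PO", ]
  snp <- snpDosage(sim2$panel)
  for (k in seq_len(nrow(po))) {
    x <- snp[po$ind1[k], ]; y <- snp[po$ind2[k], ]
    ok <- !is.na(x) & !is.na(y)
    # a PO pair shares >= 1 allele IBS at every locus: never opposite homs
    expect_true(all(abs(x[ok] - y[ok]) < 1))
  }
  # FS mean AIS strictly above the unrelated within-group background
  K <- kinshipAIS(sim2$panel)
  fs <- reg[reg$relationship == "FS", ]
  fs_ais <- mapply(function(i, j) K[i, j], fs$ind1, fs$ind2)
  grp <- indInfo(sim2$panel)$subgroup
  ids <- indIds(sim2$panel)
  rel_ids <- unique(c(reg$ind1, reg$ind2))
  bg <- c()
  for (g in unique(fs$group)) {
    mem <- setdiff(ids[grp == g], rel_ids)
    Kg <- as.matrix(K)[mem, mem]
    bg <- c(bg, Kg[upper.tri(Kg)])
  }
  expect_gt(mean(fs_ais), mean(bg))
})

test_that("requesting zero relative pairs leaves the panel unchanged", {
  sim <- simulatePanel(simulationConfig(seed = 3))
  sim2 <- injectRelatives(sim, poPerGroup = 0, fsPerGroup = 0)
  expect_identical(snpDosage(sim2$panel), snpDosage(sim$panel))
  expect_equal(nrow(sim2$truth$registry), 0)
})

test_that("phenotype simulation respects the variance decomposition limits", {
  sim <- unstructuredSim(seed = 30, n = 80, nloci = 50)
  gm <- sim$panel
  K <- kinshipAIS(gm)
  causal <- locusInfo(gm)$locus_id[3]
  # h2 = 0: pure noise with unit variance
  y0 <- simulatePhenotype(gm, K, h2 = 0, qEffect = 0.5, causal, seed = 2)
  expect_equal(stats::var(y0), 1, tolerance = 0.35)
  # qEffect = 1, h2 = 1: exactly mu + beta x
  y1 <- simulatePhenotype(gm, K, h2 = 1, qEffect = 1, causal, seed = 2, mu = 3)
  x <- snpDosage(gm)[, causal]
  beta <- sqrt(1 / stats::var(x))
  expect_equal(unname(y1), unname(3 + beta * x), tolerance = 1e-12)
  # monomorphic causal locus errors
  gmono <- makeSnpPanel(cbind(a = rep(0.5, 80)))
  expect_error(simulatePhenotype(gmono, identityK(80), 0.5, 0.1, "a", 1),
               "monomorphic")
})

test_that("regression on the causal locus recovers beta", {
  sim <- unstructuredSim(seed = 41, n = 100, nloci = 40)
  gm <- sim$panel
  K <- identityK(100, indIds(gm))
  causal <- locusInfo(gm)$locus_id[5]
  x <- snpDosage(gm)[, causal]
  h2 <- 0.5; q <- 0.3
  beta_true <- sqrt(q * h2 / stats::var(x))
  est <- vapply(seq_len(300), function(r) {
    y <- simulatePhenotype(gm, K, h2, q, causal, seed = 1000 + r)
    unname(stats::coef(stats::lm(y ~ x))[2])
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - beta_true), 2 * se + 1e-8)
})

test_that("region LD decays monotonically with distance and the wild pool halves diversity", {
  sim <- simulatePanel(simulationConfig(seed = 19))
  loc <- locusInfo(sim$panel)
  we <- which(indInfo(sim$panel)$subgroup == "WE")
  r1 <- loc$locus_id[loc$region %in% "region1"]
  ld <- pairwiseLD(sim$panel[we, ], loci = r1, minMaf = 0.05)
  bins <- cut(ld$dist_bp, c(0, 2e4, 5e4, 1e5, 2e5, 5e5, 1e6, 2e6))
  means <- tapply(ld$r2, bins, mean)
  expect_lt(stats::cor(seq_along(means), means, method = "spearman"), 0)
  expect_gt(means[1], means[length(means)])
  # wild (half-size pool) less diverse than cultivated
  cfg <- simulationConfig(seed = 20,
                          haplotypePoolSize = c(WE = 6L, WW = 6L, TE = 6L,
                                                wild = 3L))
  ds <- diversityStats(simulatePanel(cfg)$panel)
  gmn <- attr(ds, "group_means")
  expect_lt(gmn$Nei[gmn$group == "wild"],
            mean(gmn$Nei[gmn$group != "wild"]))
})

test_that("realised pairwise differentiation tracks the group targets", {
  cfg <- simulationConfig(
    seed = 44, groupSizes = c(a = 70L, b = 70L, c = 70L),
    fstTargets = c(a = 0.02, b = 0.05, c = 0.08),
    regions = data.frame(chrom = character(), start_bp = integer(),
                         length_bp = integer(), n_snps = integer()),
    nDistributedSnps = 500L, nSsr = 0L,
    haplotypePoolSize = c(a = 6L, b = 6L, c = 6L))
  sim <- simulatePanel(cfg)
  fst <- pairwiseFst(sim$panel)
  tg <- c(a = 0.02, b = 0.05, c = 0.08)
  for (g1 in c("a", "b")) for (g2 in setdiff(c("b", "c"), g1)) {
    expect_lt(abs(fst[g1, g2] - mean(tg[c(g1, g2)])), 0.02)
  }
})
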