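test_that("AIS reproduces the exhaustive two-allele table", {
  # genotypes: AA, AB, BB as dosages 0, 0.5, 1
  gm <- makeSnpPanel(cbind(a = c(0, 0, 0, 0.5, 1)))
  K <- kinshipAIS(gm)
  expect_equal(K["i01", "i02"], 1)    # AA vs AA
  expect_equal(K["i01", "i04"], 0.5)  # AA vs AB
  expect_equal(K["i04", "i04"], 0.5)  # AB self: 1 - Ho/2
  expect_equal(K["i01", "i05"], 0)    # AA vs BB
  gm2 <- makeSnpPanel(cbind(a = c(0.5, 0.5)))
  expect_equal(kinshipAIS(gm2)["i01", "i02"], 0.5) # AB vs AB
})

test_that("AIS equals the brute-force allele double loop on a mixed fixture", {
  gm <- mixedFixture(seed = 10, n = 10, nsnp = 15, nssr = 5, missRate = 0.1)
  K <- kinshipAIS(gm)
  expect_equal(unclass(as.matrix(K)), bruteAIS(gm), tolerance = 1e-12)
  # self identity: AIS(i, i) = 1 - Ho(i)/2
  snp <- snpDosage(gm); ssr <- ssrAlleles(gm)
  for (i in indIds(gm)) {
    het <- c(snp[i, ] == 0.5, ssr$a1[i, ] != ssr$a2[i, ])
    expect_equal(K[i, i], 1 - mean(het, na.rm = TRUE) / 2)
  }
})

test_that("estimators are symmetric and invariant to locus order", {
  gm <- mixedFixture(seed = 13, n = 8, nsnp = 10, nssr = 4)
  perm <- sample(seq_len(nLoci(gm)))
  gmp <- gm[, perm]
  for (f in list(kinshipAIS, kinshipLoiselle)) {
    K <- as.matrix(f(gm))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_equal(K, as.matrix(f(gmp)), tolerance = 1e-12)
  }
  grp <- rep(c("x", "y"), each = 4)
  Kw <- as.matrix(suppressWarnings(kinshipWAIS(gm, grp)))
  expect_equal(Kw, t(Kw), tolerance = 1e-12)
  expect_equal(Kw, as.matrix(suppressWarnings(kinshipWAIS(gmp, grp))),
               tolerance = 1e-12)
})

test_that("group-corrected estimators centre cross-group pairs at zero", {
  gm <- mixedFixture(seed = 16, n = 20, nsnp = 40, nssr = 5)
  grp <- rep(c("g1", "g2"), each = 10)
  cross <- outer(grp, grp, "!=")
  Kw <- as.matrix(kinshipWAIS(gm, grp))
  expect_lt(abs(mean(Kw[cross])), 1e-10)
  Kb <- as.matrix(kinshipBNO(gm, grp))
  expect_lt(abs(mean(Kb[cross])), 1e-10)
  # one group duplicated into two labels, no relatives: values around 0
  sim <- unstructuredSim(seed = 33, n = 60, nloci = 300)
  fake <- rep(c("h1", "h2"), 30)
  Kw2 <- as.matrix(kinshipWAIS(sim$panel, fake))
  off <- Kw2[upper.tri(Kw2)]
  expect_lt(abs(mean(off)), 0.01)
})

test_that("BNO matches the hand formula and collapses to WAIS for equal factors", {
  gm <- mixedFixture(seed = 18, n = 10, nsnp = 12, nssr = 0)
  grp <- rep(c("g1", "g2"), each = 5)
  Ka <- as.matrix(kinshipAIS(gm))
  # hand-computed global factor: mean per-locus AIS over cross-group pairs
  snp <- snpDosage(gm)
  cross <- which(outer(grp, grp, "!="), arr.ind = TRUE)
  vals <- c()
  for (l in seq_len(ncol(snp))) {
    x <- snp[, l]
    a <- outer(x, x) + outer(1 - x, 1 - x)
    vals <- c(vals, a[cross])
  }
  s <- mean(vals)
  Kb <- as.matrix(kinshipBNO(gm, grp))
  expect_equal(Kb, (Ka - s) / (1 - s), tolerance = 1e-12)
  # all loci identical -> every per-locus factor equals s -> WAIS == BNO
  one <- snpDosage(gm)[, 1]
  gmid <- makeSnpPanel(matrix(one, nrow = 10, ncol = 6))
  Kw <- as.matrix(kinshipWAIS(gmid, grp))
  Kb2 <- as.matrix(kinshipBNO(gmid, grp))
  expect_equal(Kw, Kb2, tolerance = 1e-12)
})

test_that("identical twins across groups score below 1 but top their row", {
  gm <- mixedFixture(seed = 25, n = 12, nsnp = 30, nssr = 5)
  # individual 1 duplicated as individual 7 (other group)
  gm@snp[7, ] <- gm@snp[1, ]
  gm@ssrA[7, ] <- gm@ssrA[1, ]
  gm@ssrB[7, ] <- gm@ssrB[1, ]
  grp <- rep(c("g1", "g2"), each = 6)
  Kw <- as.matrix(suppressWarnings(kinshipWAIS(gm, grp)))
  off <- Kw[1, -1]
  expect_lt(Kw[1, 7], 1)
  expect_equal(unname(which.max(off)), which(indIds(gm)[-1] == "i07"))
})

test_that("Loiselle centres unrelated panels, tracks duplicates, ignores labels", {
  sim <- unstructuredSim(seed = 52, n = 60, nloci = 500)
  K <- as.matrix(kinshipLoiselle(sim$panel))
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.01)
  # duplicated individual: near the self value and maximal in its row
  gm <- mixedFixture(seed = 26, n = 10, nsnp = 40, nssr = 5)
  gm@snp[10, ] <- gm@snp[1, ]
  gm@ssrA[10, ] <- gm@ssrA[1, ]
  gm@ssrB[10, ] <- gm@ssrB[1, ]
  Kd <- as.matrix(kinshipLoiselle(gm))
  expect_equal(Kd["i01", "i10"], Kd["i01", "i01"], tolerance = 1e-9)
  expect_equal(unname(which.max(Kd[1, -1])), which(indIds(gm)[-1] == "i10"))
  # allele relabelling invariance (swap ref/alt on all SNPs; relabel SSRs)
  gm2 <- gm
  gm2@snp <- 1 - gm@snp
  gm2@ssrA <- 10L - gm@ssrB # order flips: canonicalise through constructor
  gm2@ssrB <- 10L - gm@ssrA
  expect_equal(as.matrix(kinshipLoiselle(gm2)), Kd, tolerance = 1e-12)
})

test_that("MLE likelihood at the optimum dominates the fixed hypotheses", {
  gm <- mixedFixture(seed = 29, n = 8, nsnp = 25, nssr = 5)
  pairs <- cbind(1:4, 5:8)
  mle <- suppressWarnings(kinshipMLE(gm, pairs = pairs))
  calls <- classifyRelationship(gm, pairs = pairs)
  expect_true(all(mle$logLik >= calls$ll_U - 1e-6))
  expect_true(all(mle$logLik >= calls$ll_PO - 1e-6))
  expect_true(all(mle$k0 >= 0 & mle$k0 <= 1))
  expect_equal(mle$k0 + mle$k1 + mle$k2, rep(1, 4), tolerance = 1e-9)
})

test_that("MLE recovers PO and unrelated coancestry on matched simulations", {
  sim <- unstructuredSim(seed = 61, n = 80, nloci = 500)
  sim <- injectRelatives(sim, poPerGroup = 8, fsPerGroup = 0, groups = "P")
  reg <- sim$truth$registry
  mle <- suppressWarnings(
    kinshipMLE(sim$panel, pairs = as.matrix(reg[, c("ind1", "ind2")])))
  expect_lt(abs(mean(mle$kinship) - 0.25), 0.05)
  ids <- setdiff(indIds(sim$panel), c(reg$ind1, reg$ind2))
  unrel <- cbind(ids[1:20], ids[21:40])
  mleu <- suppressWarnings(kinshipMLE(sim$panel, pairs = unrel))
  expect_lt(mean(mleu$kinship), 0.05)
  expect_gt(mean(mleu$k0), 0.8)
})

test_that("relationship calls honour Mendelian exclusion and tie preference", {
  # opposite homozygotes at one locus: PO impossible
  gm <- makeSnpPanel(cbind(a = c(0, 1), b = c(0.5, 0.5), c = c(0, 0)))
  calls <- suppressWarnings(classifyRelationship(gm, pairs = cbind(1, 2)))
  expect_equal(calls$ll_PO, -Inf)
  expect_false(calls$best == "PO")
  # identical monomorphic data: all hypotheses tie -> U preferred
  gm2 <- makeSnpPanel(cbind(a = c(0, 0), b = c(0, 0)))
  calls2 <- suppressWarnings(classifyRelationship(gm2, pairs = cbind(1, 2)))
  expect_equal(calls2$best, "U")
})

test_that("injected first-degree pairs are flagged and unrelated pairs are not", {
  sim <- unstructuredSim(seed = 71, n = 90, nloci = 129, nssr = 20)
  sim <- injectRelatives(sim, poPerGroup = 8, fsPerGroup = 8, groups = "P")
  reg <- sim$truth$registry
  calls <- classifyRelationship(sim$panel,
                                pairs = as.matrix(reg[, c("ind1", "ind2")]))
  expect_gte(mean(calls$first_degree), 0.9)
  ids <- setdiff(indIds(sim$panel), c(reg$ind1, reg$ind2))
  unrel <- cbind(ids[1:12], ids[13:24])
  callsu <- classifyRelationship(sim$panel, pairs = unrel)
  expect_lte(mean(callsu$first_degree), 0.1)
})

test_that("estimator selection is an argmin with the documented tie-break", {
  sim <- simulatePanel(simulationConfig(seed = 37))
  gm <- sim$panel
  grp <- indInfo(gm)$subgroup
  loc <- locusInfo(gm)
  ksel <- loc$locus_id[loc$region %in% "distributed" | loc$locus_type == "ssr"]
  kgm <- gm[, ksel]
  cands <- list(kinshipAIS(kgm),
                suppressWarnings(kinshipWAIS(kgm, grp)),
                identityK(nInd(gm), indIds(gm)))
  rsel <- loc$locus_id[grepl("^region", loc$region)]
  win <- selectEstimatorByInterchromLD(gm, cands, loci = rsel)
  means <- attr(win, "mean_interchrom_ld")
  expect_lte(means[win], means["identity"])
  expect_equal(unname(means[win]), min(means))
  # ties broken by tag order: duplicate candidates under different tags
  K1 <- kinshipAIS(kgm)
  K2 <- KinshipMatrix(as.matrix(K1), "LOI")
  win2 <- selectEstimatorByInterchromLD(gm, list(K2, K1), loci = rsel)
  expect_equal(as.character(win2), "AIS")
})
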