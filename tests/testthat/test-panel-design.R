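test_that("simple matching dissimilarity has its fixed points and oracle", {
  gm <- makeSnpPanel(rbind(i1 = c(0, 0, 1), i2 = c(0, 0, 1),
                           i3 = c(1, 1, 0)))
  D <- simpleMatchingDissimilarity(gm)
  expect_equal(D["i1", "i2"], 0)  # identical individuals
  expect_equal(D["i1", "i3"], 1)  # opposite homozygotes everywhere
  expect_equal(diag(D), setNames(rep(0, 3), rownames(D)))
  # brute-force allele matching on a 5 x 10 mixed fixture
  gm2 <- mixedFixture(seed = 35, n = 5, nsnp = 7, nssr = 3, missRate = 0.1)
  D2 <- simpleMatchingDissimilarity(gm2)
  als <- alleleLists(gm2)
  ids <- names(als)
  for (i in 1:4) for (j in (i + 1):5) {
    vals <- c()
    for (l in names(als[[i]])) {
      gi <- als[[i]][[l]]; gj <- als[[j]][[l]]
      if (is.null(gi) || is.null(gj)) next
      # best assignment of the two alleles
      m <- max((gi[1] == gj[1]) + (gi[2] == gj[2]),
               (gi[1] == gj[2]) + (gi[2] == gj[1]))
      vals <- c(vals, m / 2)
    }
    expect_equal(D2[ids[i], ids[j]], 1 - mean(vals), tolerance = 1e-12)
  }
})

test_that("maximin subsampling picks extremes and beats random subsets", {
  # 1-D points 0, 1, 10: the m = 2 solution is the farthest pair
  D <- as.matrix(stats::dist(c(a = 0, b = 1, c = 10)))
  expect_setequal(maximinSubsample(D, 2), c("a", "c"))
  # m = all candidates returns the full set
  expect_setequal(maximinSubsample(D, 3), c("a", "b", "c"))
  expect_error(maximinSubsample(D, 4), "exceeds")
  # mandatory ids are seeded first
  sel <- maximinSubsample(D, 2, mandatory = "b")
  expect_equal(sel[1], "b")
  # random-baseline oracle on a 100-candidate fixture
  set.seed(77)
  pts <- matrix(rnorm(200), 100)
  rownames(pts) <- sprintf("c%03d", 1:100)
  Dm <- as.matrix(stats::dist(pts))
  sel <- maximinSubsample(Dm, 10)
  score <- function(s) min(Dm[s, s][upper.tri(diag(length(s)))])
  rand <- vapply(seq_len(1000), function(r)
    score(sample(rownames(Dm), 10)), numeric(1))
  expect_gte(score(sel), max(rand))
  # invariance to candidate input order
  perm <- sample(100)
  expect_setequal(maximinSubsample(Dm[perm, perm], 10), sel)
})

test_that("panel design without relatives is a single maximin pass", {
  sim <- simulatePanel(simulationConfig(seed = 51))
  gm <- sim$panel
  founders <- indIds(gm)[c(2, 100)]
  ps <- designPanel(gm, sim$Q, founders = founders, subgroupSize = 20,
                    subgroups = c("WE", "WW", "TE"))
  sizes <- vapply(ps@selection, length, integer(1))
  expect_equal(unname(sizes), rep(20L, 3))
  expect_true(all(founders %in% panelIds(ps)))
  expect_true(all(!duplicated(panelIds(ps))))
  # selections live in their own subgroups
  grp <- setNames(indInfo(gm)$subgroup, indIds(gm))
  for (g in names(ps@selection)) {
    expect_true(all(grp[ps@selection[[g]]] == g))
  }
})

test_that("a planted PO pair is pruned, the founder retained, the panel clean", {
  # a parent (founder) and its child both carry a block of alleles rare in
  # the rest of the collection, so the maximin fill must select both; the
  # pruning loop then has to evict the child and refill
  set.seed(31)
  n <- 24; L <- 80
  p <- c(rep(0.05, 30), rep(0.5, 50))
  X <- sapply(p, function(pp) rbinom(n, 2, pp) / 2)
  X[1, 1:30] <- 1                       # parent: hom for the rare block
  parent_gam <- rbinom(L, 1, X[1, ])    # child: one parental gamete
  other_gam <- rbinom(L, 1, p)
  X[2, ] <- (parent_gam + other_gam) / 2
  gm <- makeSnpPanel(X)
  Q <- structureMatrix(matrix(1, n, 1,
                              dimnames = list(indIds(gm), "g1")), "g1")
  ps <- designPanel(gm, Q, founders = "i01", subgroupSize = 12,
                    subgroups = "g1")
  ids <- panelIds(ps)
  expect_equal(length(ids), 12)
  expect_true("i01" %in% ids)           # founder parent retained
  expect_false("i02" %in% ids)          # non-founder child evicted
  expect_gt(nrow(ps@log), 0)
  calls <- classifyRelationship(gm[ids, ])
  expect_equal(sum(calls$first_degree), 0)
})

test_that("representativeness of the full collection is perfect by construction", {
  gm <- mixedFixture(seed = 58, n = 30, nsnp = 20, nssr = 6)
  set.seed(1)
  ph <- data.frame(ind_id = indIds(gm), t1 = rnorm(30), t2 = rnorm(30, 5, 2))
  rep <- assessRepresentativeness(indIds(gm), gm, phenotypes = ph)
  expect_equal(rep$allele_retention, 1)
  expect_equal(rep$freq_r2, 1)
  expect_equal(rep$traits$var_captured, c(1, 1))
  expect_true(all(rep$traits$ranksum_p > 0.9))
})

test_that("only rare alleles may be lost without hurting retention", {
  # panel misses exactly the alleles that are rare in the collection
  a1 <- matrix(c(rep(1L, 18), 3L, 4L), 20)
  a2 <- matrix(c(rep(2L, 18), 3L, 4L), 20)
  gm <- makeSsrPanel(a1, a2)
  panel <- indIds(gm)[1:18] # drops carriers of rare alleles 3 and 4
  rep <- assessRepresentativeness(panel, gm, rareMaf = 0.05)
  expect_equal(rep$allele_retention, 1)
})

test_that("the rank-sum p-value matches an exact permutation oracle", {
  x <- c(-2.4, -2.1, -2, -1.5, -0.8, 0.8, 1.7, 2.9)
  y <- c(-3.6, 0.3, 1.8, 2.1, 2.3, 4.2, 4.4, 6)
  got <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  # enumerate all assignments of 8 of the 16 values to the first sample
  pool <- c(x, y)
  W_obs <- sum(rank(pool)[1:8]) - 8 * 9 / 2
  combos <- utils::combn(16, 8)
  W_all <- apply(combos, 2, function(idx) sum(rank(pool)[idx]) - 8 * 9 / 2)
  exact_p <- mean(abs(W_all - mean(W_all)) >= abs(W_obs - mean(W_all)) - 1e-9)
  expect_lt(abs(got - exact_p), 0.01)
})

test_that("designed panels retain common alleles at least as well as random ones", {
  set.seed(63)
  better <- vapply(seq_len(5), function(r) {
    cfg <- simulationConfig(seed = 200 + r, groupSizes = c(WE = 80L),
                            fstTargets = c(WE = 0.03),
                            haplotypePoolSize = c(WE = 6L))
    sim <- simulatePanel(cfg)
    gm <- sim$panel
    ps <- designPanel(gm, sim$Q, subgroupSize = 25, subgroups = "WE")
    ret <- assessRepresentativeness(panelIds(ps), gm)$allele_retention
    rnd <- assessRepresentativeness(sample(indIds(gm), 25), gm)$allele_retention
    ret - rnd
  }, numeric(1))
  expect_gte(mean(better), 0)
})
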