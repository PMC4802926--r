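test_that("VCF GT codes map to the dosage alphabet", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("chr1", "100", "locA", "A", "G", ".", ".", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("chr1", "250", "locB", "T", "C", ".", ".", ".", "GT",
            "./.", "1|0", "0/0"), collapse = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gm <- readGenotypes(f, "vcf")
  expect_equal(unname(snpDosage(gm)[, "locA"]), c(0, 0.5, 1))
  expect_equal(unname(snpDosage(gm)[, "locB"]), c(NA, 0.5, 0))
  expect_equal(locusInfo(gm)$pos_bp, c(100L, 250L))

  vcf_multi <- sub("\tG\t", "\tG,T\t", vcf[4])
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf[1:3], vcf_multi, vcf[5]), f2)
  expect_error(readGenotypes(f2, "vcf"), "multiallelic")
})

test_that("round-trip write/read is lossless for all three formats", {
  gm <- mixedFixture(seed = 3, n = 8, nsnp = 10, nssr = 4, missRate = 0.15)
  fd <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypes(gm, fd, "dosage_table")
  back <- readGenotypes(fd, "dosage_table")
  expect_identical(unname(snpDosage(back)), unname(snpDosage(gm)))
  expect_identical(indIds(back), indIds(gm))

  fs <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypes(gm, fs, "ssr_table")
  back <- readGenotypes(fs, "ssr_table")
  expect_identical(unname(ssrAlleles(back)$a1), unname(ssrAlleles(gm)$a1))
  expect_identical(unname(ssrAlleles(back)$a2), unname(ssrAlleles(gm)$a2))

  fv <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypes(gm, fv, "vcf")
  back <- readGenotypes(fv, "vcf")
  expect_identical(unname(snpDosage(back)), unname(snpDosage(gm)))
  snp_loc <- locusInfo(gm)[locusInfo(gm)$locus_type == "snp", ]
  expect_identical(locusInfo(back)$pos_bp, snp_loc$pos_bp)
})

test_that("a dosage table NA cell stays missing and bad dosages are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ind_id\ta\tb", "i1\t0\tNA", "i2\t0.5\t1"), f)
  gm <- readGenotypes(f, "dosage_table")
  expect_true(is.na(snpDosage(gm)["i1", "b"]))
  expect_equal(snpDosage(gm)["i2", "a"], 0.5)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ind_id\ta", "i1\t0.7"), f2)
  expect_error(readGenotypes(f2, "dosage_table"), "invalid dosage")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ind_id\ta", "i1\t0", "i1\t1"), f3)
  expect_error(readGenotypes(f3, "dosage_table"), "duplicated")
})

test_that("locus filtering matches a brute-force recount and is idempotent", {
  set.seed(11)
  n <- 40; L <- 500
  p <- runif(L, 0.01, 0.5)
  X <- sapply(p, function(pp) rbinom(n, 2, pp) / 2)
  X[matrix(runif(n * L) < 0.1, n, L)] <- NA
  gm <- makeSnpPanel(X)
  out <- suppressWarnings(filterLoci(gm, maxMissing = 0.08, minMaf = 0.05))
  # independent recount
  keep <- logical(L)
  for (j in seq_len(L)) {
    x <- X[, j]
    miss <- mean(is.na(x))
    pj <- mean(x, na.rm = TRUE)
    keep[j] <- miss <= 0.08 && min(pj, 1 - pj) >= 0.05
  }
  expect_identical(locusInfo(out)$locus_id, locusInfo(gm)$locus_id[keep])
  twice <- suppressWarnings(filterLoci(out, maxMissing = 0.08, minMaf = 0.05))
  expect_identical(snpDosage(twice), snpDosage(out))
  # minMaf = 0: only the missingness filter applies
  only_miss <- filterLoci(gm, maxMissing = 0.08, minMaf = 0)
  expect_equal(nLoci(only_miss), sum(colMeans(is.na(X)) <= 0.08))
})

test_that("individual filtering applies the membership threshold and assigns subgroups", {
  gm <- mixedFixture(seed = 5, n = 3, nsnp = 6, nssr = 0)
  Q <- structureMatrix(rbind(c(0.85, 0.10, 0.05),
                             c(0.50, 0.30, 0.20),
                             c(0.05, 0.90, 0.05)),
                       c("g1", "g2", "g3"))
  rownames(Q) <- indIds(gm)
  out <- filterIndividuals(gm, Q, minMembership = 0.8)
  expect_identical(indIds(out), c("i01", "i03"))
  expect_identical(indInfo(out)$subgroup, c("g1", "g2"))

  # counting oracle on a larger simulated Q
  set.seed(7)
  n <- 200
  Qm <- t(apply(matrix(rgamma(n * 3, 0.5), n), 1, function(r) r / sum(r)))
  gm2 <- makeSnpPanel(matrix(sample(c(0, 0.5, 1), n * 5, TRUE), n))
  rownames(Qm) <- indIds(gm2)
  out2 <- filterIndividuals(gm2, structureMatrix(Qm, c("a", "b", "c")),
                            minMembership = 0.8)
  expect_equal(nInd(out2), sum(apply(Qm, 1, max) >= 0.8))
})

test_that("the dosage alphabet is closed under filtering and subsetting", {
  gm <- mixedFixture(seed = 9, n = 12, nsnp = 20, nssr = 3, missRate = 0.2)
  out <- suppressWarnings(filterLoci(gm, maxMissing = 0.5, minMaf = 0.05))
  vals <- snpDosage(out[seq_len(6), ])
  expect_true(all(vals[!is.na(vals)] %in% c(0, 0.5, 1)))
})
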