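# deterministic in-code fixtures shared across the suite

makeSnpPanel <- function(dosage, chrom = "chr1", pos = NULL,
                         region = NA_character_, subgroup = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("i%02d", seq_len(nrow(dosage)))
  if (is.null(pos)) pos <- seq_len(ncol(dosage)) * 100L
  ind <- data.frame(ind_id = rownames(dosage))
  if (!is.null(subgroup)) ind$subgroup <- subgroup
  GenotypePanel(
    snp = dosage,
    loci = data.frame(locus_id = colnames(dosage), chrom = chrom,
                      pos_bp = pos, locus_type = "snp", region = region),
    individuals = ind)
}

makeSsrPanel <- function(a1, a2, subgroup = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (is.null(colnames(a1)))
    colnames(a1) <- colnames(a2) <- sprintf("m%02d", seq_len(ncol(a1)))
  if (is.null(rownames(a1)))
    rownames(a1) <- rownames(a2) <- sprintf("i%02d", seq_len(nrow(a1)))
  ind <- data.frame(ind_id = rownames(a1))
  if (!is.null(subgroup)) ind$subgroup <- subgroup
  GenotypePanel(ssr = list(a1 = a1, a2 = a2), individuals = ind)
}

# random mixed SNP+SSR panel with optional missingness
mixedFixture <- function(seed = 1, n = 10, nsnp = 15, nssr = 5,
                         missRate = 0) {
  set.seed(seed)
  snp <- matrix(sample(c(0, 0.5, 1), n * nsnp, TRUE), n, nsnp)
  a1 <- matrix(sample.int(6, n * nssr, TRUE), n, nssr)
  a2 <- matrix(sample.int(6, n * nssr, TRUE), n, nssr)
  if (missRate > 0) {
    snp[matrix(runif(n * nsnp) < missRate, n, nsnp)] <- NA
    mm <- matrix(runif(n * nssr) < missRate, n, nssr)
    a1[mm] <- NA; a2[mm] <- NA
  }
  colnames(snp) <- sprintf("s%02d", seq_len(nsnp))
  colnames(a1) <- colnames(a2) <- sprintf("m%02d", seq_len(nssr))
  rownames(snp) <- rownames(a1) <- rownames(a2) <- sprintf("i%02d", seq_len(n))
  loci <- data.frame(
    locus_id = c(colnames(snp), colnames(a1)),
    chrom = rep(c("chr1", "chr2"), length.out = nsnp + nssr),
    pos_bp = seq_len(nsnp + nssr) * 1000L,
    locus_type = rep(c("snp", "ssr"), c(nsnp, nssr)),
    region = NA_character_)
  GenotypePanel(snp = snp, ssr = list(a1 = a1, a2 = a2), loci = loci,
                individuals = data.frame(ind_id = rownames(snp)))
}

identityK <- function(n, ids = sprintf("i%02d", seq_len(n))) {
  KinshipMatrix(matrix(diag(n), n, n, dimnames = list(ids, ids)), "identity")
}

# per-individual allele lists, the shared representation for brute-force
# oracles (SNP alleles "A"/"B"; SSR alleles as character labels)
alleleLists <- function(gm) {
  ids <- indIds(gm)
  loc <- locusInfo(gm)
  snp <- snpDosage(gm); ssr <- ssrAlleles(gm)
  out <- lapply(ids, function(i) {
    al <- list()
    for (l in colnames(snp)) {
      x <- snp[i, l]
      al[[l]] <- if (is.na(x)) NULL else
        c(rep("A", 2 - 2 * x), rep("B", 2 * x))
    }
    for (l in colnames(ssr$a1)) {
      a <- ssr$a1[i, l]
      al[[l]] <- if (is.na(a)) NULL else
        as.character(c(a, ssr$a2[i, l]))
    }
    al
  })
  names(out) <- ids
  out
}

# brute-force AIS over allele lists: mean over shared loci of the fraction
# of matching ordered allele comparisons
bruteAIS <- function(gm) {
  als <- alleleLists(gm)
  ids <- names(als)
  n <- length(ids)
  out <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    vals <- c()
    for (l in names(als[[i]])) {
      gi <- als[[i]][[l]]; gj <- als[[j]][[l]]
      if (is.null(gi) || is.null(gj)) next
      m <- 0
      for (a in gi) for (b in gj) m <- m + (a == b)
      vals <- c(vals, m / 4)
    }
    if (length(vals)) out[i, j] <- mean(vals)
  }
  out
}

# a small single-population panel of independent loci (for estimator
# recovery under matched assumptions)
unstructuredSim <- function(seed, n = 60, nloci = 300, nssr = 0) {
  simulatePanel(simulationConfig(
    seed = seed, groupSizes = c(P = as.integer(n)), fstTargets = c(P = 0),
    regions = data.frame(chrom = character(), start_bp = integer(),
                         length_bp = integer(), n_snps = integer()),
    nDistributedSnps = as.integer(nloci), nSsr = as.integer(nssr),
    haplotypePoolSize = c(P = 6L)))
}
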