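#' @include genotypes-io.R
NULL

# internal: per-locus individual allele-count matrices (N x A, counts in
# {0,1,2}; NA rows for missing calls) plus allele labels; SNP alleles are
# labelled "ref"/"alt".
.alleleCounts <- function(gm) {
  out <- vector("list", nLoci(gm))
  names(out) <- gm@loci$locus_id
  for (l in colnames(gm@snp)) {
    x <- gm@snp[, l]
    cnt <- cbind(ref = 2 - 2 * x, alt = 2 * x)
    rownames(cnt) <- indIds(gm)
    out[[l]] <- cnt
  }
  for (l in colnames(gm@ssrA)) {
    a <- gm@ssrA[, l]; b <- gm@ssrB[, l]
    alleles <- sort(unique(c(a, b)))
    alleles <- alleles[!is.na(alleles)]
    cnt <- matrix(0, nrow = nInd(gm), ncol = length(alleles),
                  dimnames = list(indIds(gm), as.character(alleles)))
    for (j in seq_along(alleles)) {
      cnt[, j] <- (a == alleles[j]) + (b == alleles[j])
    }
    cnt[is.na(a), ] <- NA_real_
    out[[l]] <- cnt
  }
  out
}

#' Per-locus allele frequencies
#'
#' Frequencies are computed from non-missing calls only. SNP loci report the
#' "ref"/"alt" pair (alt = dosage mean); SSR loci report the full allele
#' spectrum. A locus with all calls missing is reported with frequency NA.
#'
#' @param gm a [GenotypePanel-class].
#' @param group optional subgroup label; restricts to individuals with that
#'   subgroup (at least 2 required).
#' @return data.frame with columns \code{locus_id}, \code{allele},
#'   \code{freq}, \code{n_calls}.
#' @export
alleleFrequencies <- function(gm, group = NULL) {
  if (!is.null(group)) {
    keep <- which(gm@individuals$subgroup %in% group)
    if (length(keep) < 2) stop("group must match at least 2 individuals")
    gm <- gm[keep, ]
  }
  counts <- .alleleCounts(gm)
  res <- lapply(names(counts), function(l) {
    cnt <- counts[[l]]
    ok <- !is.na(cnt[, 1])
    n <- sum(ok)
    f <- if (n) colSums(cnt[ok, , drop = FALSE]) / (2 * n) else rep(NA_real_, ncol(cnt))
    data.frame(locus_id = l, allele = colnames(cnt), freq = unname(f),
               n_calls = n)
  })
  do.call(rbind, res)
}

# observed heterozygosity per locus on a panel subset
.obsHet <- function(gm) {
  out <- setNames(rep(NA_real_, nLoci(gm)), gm@loci$locus_id)
  if (ncol(gm@snp))
    out[colnames(gm@snp)] <- colMeans(gm@snp == 0.5, na.rm = TRUE)
  if (ncol(gm@ssrA))
    out[colnames(gm@ssrA)] <- colMeans(gm@ssrA != gm@ssrB, na.rm = TRUE)
  out
}

#' Per-locus, per-group diversity statistics
#'
#' For every locus and group: number of alleles observed (Na), effective
#' number of alleles Ne = 1 / sum(p_i^2), expected heterozygosity
#' He = 1 - sum(p_i^2) (no small-sample correction), observed heterozygosity
#' Ho (fraction of heterozygous non-missing calls), minor allele frequency,
#' and Nei's diversity index (equal to He). Group means average each
#' statistic over loci with a defined value.
#'
#' @param gm a [GenotypePanel-class].
#' @param groups per-individual group labels (default: the panel's subgroup
#'   column); NA-labelled individuals are ignored. Use a single shared label
#'   to get whole-panel statistics.
#' @return data.frame (group x locus rows) with the statistics; the per-group
#'   means over loci are in \code{attr(, "group_means")}.
#' @export
diversityStats <- function(gm, groups = indInfo(gm)$subgroup) {
  groups <- as.character(groups)
  if (length(groups) != nInd(gm)) stop("groups must label every individual")
  labs <- unique(groups[!is.na(groups)])
  rows <- list()
  for (g in labs) {
    sub <- gm[which(groups == g), ]
    counts <- .alleleCounts(sub)
    ho <- .obsHet(sub)
    maf <- .locusMaf(sub)
    for (l in names(counts)) {
      cnt <- counts[[l]]
      ok <- !is.na(cnt[, 1])
      if (!sum(ok)) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, locus_id = l, Na = NA_integer_, Ne = NA_real_,
          He = NA_real_, Ho = NA_real_, MAF = NA_real_, Nei = NA_real_)
        next
      }
      f <- colSums(cnt[ok, , drop = FALSE]) / (2 * sum(ok))
      f <- f[f > 0]
      sumsq <- sum(f^2)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, locus_id = l, Na = length(f), Ne = 1 / sumsq,
        He = 1 - sumsq, Ho = unname(ho[l]), MAF = unname(maf[l]),
        Nei = 1 - sumsq)
    }
  }
  out <- do.call(rbind, rows)
  num <- c("Na", "Ne", "He", "Ho", "MAF", "Nei")
  gmeans <- do.call(rbind, lapply(split(out[num], out$group), function(d)
    as.data.frame(lapply(d, mean, na.rm = TRUE))))
  gmeans <- data.frame(group = rownames(gmeans), gmeans, row.names = NULL)
  attr(out, "group_means") <- gmeans
  out
}

# Weir & Cockerham (1984) variance components for one locus and one allele,
# over r groups; returns c(a, b, c) or NULL when undefined.
.wcComponents <- function(p, h, n) {
  ok <- n > 0
  p <- p[ok]; h <- h[ok]; n <- n[ok]
  r <- length(n)
  if (r < 2) return(NULL)
  nbar <- mean(n)
  if (nbar <= 1) return(NULL)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  if (nc <= 0) return(NULL)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a, b, cc)
}

#' Pairwise Weir-Cockerham differentiation between groups
#'
#' Pairwise Fst as Weir & Cockerham's (1984) theta, combined over loci and
#' alleles by ratio of sums of the a, b, c variance components. Negative
#' estimates are reported as computed. Groups with fewer than 2 genotyped
#' individuals are excluded with a warning.
#'
#' @param gm a [GenotypePanel-class].
#' @param groups per-individual group labels (default: subgroup column).
#' @param perLocus also return the per-locus theta array?
#' @return symmetric labelled matrix of pairwise theta (diagonal 0); when
#'   \code{perLocus}, the per-locus estimates are in
#'   \code{attr(, "per_locus")}.
#' @export
pairwiseFst <- function(gm, groups = indInfo(gm)$subgroup, perLocus = FALSE) {
  groups <- as.character(groups)
  tab <- table(groups[!is.na(groups)])
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning(sprintf("excluding groups with < 2 individuals: %s",
                    paste(small, collapse = ", ")))
  }
  labs <- names(tab)[tab >= 2]
  if (length(labs) < 2) stop("need at least 2 groups of size >= 2")
  counts <- .alleleCounts(gm)
  fst <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  pl <- if (perLocus) array(NA_real_, c(length(counts), length(labs), length(labs)),
                            dimnames = list(names(counts), labs, labs)) else NULL
  idx <- lapply(labs, function(g) which(groups == g))
  names(idx) <- labs
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      num <- den <- 0
      for (l in names(counts)) {
        cnt <- counts[[l]]
        num_l <- den_l <- 0
        for (al in seq_len(ncol(cnt))) {
          x1 <- cnt[idx[[i]], al]; x2 <- cnt[idx[[j]], al]
          n <- c(sum(!is.na(x1)), sum(!is.na(x2)))
          if (any(n < 1)) next
          p <- c(mean(x1, na.rm = TRUE), mean(x2, na.rm = TRUE)) / 2
          h <- c(mean(x1 == 1, na.rm = TRUE), mean(x2 == 1, na.rm = TRUE))
          comp <- .wcComponents(p, h, n)
          if (is.null(comp)) next
          num_l <- num_l + comp[1]
          den_l <- den_l + sum(comp)
        }
        num <- num + num_l; den <- den + den_l
        if (perLocus && den_l > 0)
          pl[l, labs[i], labs[j]] <- pl[l, labs[j], labs[i]] <- num_l / den_l
      }
      fst[i, j] <- fst[j, i] <- if (den > 0) num / den else NA_real_
    }
  }
  if (perLocus) attr(fst, "per_locus") <- pl
  fst
}

#' SNP density per window of sequence
#'
#' Simple discovery-rate summary: number of SNPs per \code{per} bp of
#' surveyed sequence.
#'
#' @param nSnps number of SNPs observed.
#' @param totalBp total surveyed length in bp.
#' @param per reporting window in bp (default 100).
#' @return SNPs per \code{per} bp.
#' @export
snpDensity <- function(nSnps, totalBp, per = 100) {
  stopifnot(nSnps >= 0, totalBp > 0)
  nSnps / totalBp * per
}
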