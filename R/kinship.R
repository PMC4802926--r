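#' @include synthetic-panel.R
NULL

# per-locus alikeness-in-state matrix (N x N, NA where either call missing)
# for SNP dosage x: AIS(i,j) = x_i x_j + (1 - x_i)(1 - x_j) scaled to allele
# comparisons, i.e. 1/4 of the four inter-individual allele matches.
.aisLocusSnp <- function(x) {
  n <- length(x)
  one <- rep(1, n)
  out <- 2 * tcrossprod(x) - outer(x, one) - outer(one, x) + 1
  out[is.na(x), ] <- NA_real_
  out[, is.na(x)] <- NA_real_
  out
}

.aisLocusSsr <- function(a, b) {
  out <- (outer(a, a, "==") + outer(a, b, "==") +
          outer(b, a, "==") + outer(b, b, "==")) / 4
  out[is.na(a), ] <- NA_real_
  out[, is.na(a)] <- NA_real_
  out
}

# iterate per-locus AIS matrices, calling f(aisMatrix, locus_id) for each
.forEachAisLocus <- function(gm, f) {
  for (l in colnames(gm@snp)) f(.aisLocusSnp(gm@snp[, l]), l)
  for (l in colnames(gm@ssrA)) f(.aisLocusSsr(gm@ssrA[, l], gm@ssrB[, l]), l)
  invisible(NULL)
}

#' Alikeness-in-state coancestry
#'
#' For genotypes (a,b) and (c,d), the per-locus alikeness in state is
#' (I(a=c) + I(a=d) + I(b=c) + I(b=d)) / 4 -- the probability that one
#' allele drawn from each individual is identical by state -- averaged over
#' loci non-missing in both individuals. SNP and SSR loci contribute
#' equally. The diagonal holds each individual's self value,
#' 1 - Ho(individual)/2.
#'
#' @param gm a [GenotypePanel-class].
#' @return a [KinshipMatrix-class] tagged "AIS" (entries in [0, 1]; NA for
#'   pairs sharing no genotyped locus, with a warning).
#' @export
kinshipAIS <- function(gm) {
  n <- nInd(gm)
  num <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  .forEachAisLocus(gm, function(a, l) {
    ok <- !is.na(a)
    a[!ok] <- 0
    num <<- num + a
    cnt <<- cnt + ok
  })
  out <- num / cnt
  if (any(cnt == 0))
    warning("some pairs share no genotyped locus; AIS entry set to NA")
  dimnames(out) <- list(indIds(gm), indIds(gm))
  KinshipMatrix(out, "AIS")
}

# shared engine for the group-corrected estimators: perLocus = TRUE gives
# WAIS (one correction factor per locus), FALSE gives BNO (one global
# factor); the factor is the mean AIS over cross-group pairs, the mean
# probability that two individuals from groups assumed unrelated share an
# IBS allele that is not IBD.
.kinshipGroupCorrected <- function(gm, unrelatedGroups, perLocus) {
  grp <- as.character(unrelatedGroups)
  if (length(grp) != nInd(gm))
    stop("unrelatedGroups must label every individual")
  if (length(unique(grp[!is.na(grp)])) < 2)
    stop("need at least 2 unrelated groups")
  n <- nInd(gm)
  cross <- outer(grp, grp, "!=")
  cross[is.na(cross)] <- FALSE
  num <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  s_num <- 0; s_den <- 0
  skipped <- 0L
  store <- if (perLocus) NULL else list(ais_num = matrix(0, n, n),
                                        ais_cnt = matrix(0L, n, n))
  .forEachAisLocus(gm, function(a, l) {
    ok <- !is.na(a)
    use <- ok & cross
    if (!any(use)) return(invisible(NULL))
    s_l <- mean(a[use])
    if (perLocus) {
      if (s_l >= 1 - 1e-12) {
        skipped <<- skipped + 1L
        return(invisible(NULL))
      }
      a0 <- a; a0[!ok] <- 0
      num <<- num + (a0 - s_l) / (1 - s_l) * ok
      cnt <<- cnt + ok
    } else {
      s_num <<- s_num + sum(a[use])
      s_den <<- s_den + sum(use)
      a0 <- a; a0[!ok] <- 0
      store$ais_num <<- store$ais_num + a0
      store$ais_cnt <<- store$ais_cnt + ok
    }
    invisible(NULL)
  })
  if (perLocus) {
    if (skipped)
      warning(sprintf("%d loci skipped (cross-group mean AIS = 1)", skipped))
    out <- num / cnt
  } else {
    s <- s_num / s_den
    if (s >= 1 - 1e-12) stop("degenerate data: global cross-group AIS = 1")
    out <- (store$ais_num / store$ais_cnt - s) / (1 - s)
  }
  dimnames(out) <- list(indIds(gm), indIds(gm))
  out
}

#' Weighted alikeness-in-state coancestry (per-locus correction)
#'
#' AIS corrected by per-locus factors: at each locus, the mean AIS over all
#' pairs of individuals from different assumed-unrelated groups (s_l) is the
#' expected IBS sharing that is not IBD; the corrected per-pair value is the
#' mean over loci of (AIS_l - s_l) / (1 - s_l). Tagged "WAIS2" or "WAIS4"
#' by group count. Negative values are retained (see
#' [KinshipMatrix-class]).
#'
#' @param gm a [GenotypePanel-class].
#' @param unrelatedGroups per-individual group labels (2 or 4 groups in the
#'   standard workflow).
#' @return a [KinshipMatrix-class].
#' @export
kinshipWAIS <- function(gm, unrelatedGroups) {
  out <- .kinshipGroupCorrected(gm, unrelatedGroups, perLocus = TRUE)
  ngrp <- length(unique(unrelatedGroups[!is.na(unrelatedGroups)]))
  KinshipMatrix(out, if (ngrp == 2) "WAIS2" else "WAIS4",
                as.character(unrelatedGroups))
}

#' Group-corrected coancestry with a single global factor
#'
#' As [kinshipWAIS()] but with one global correction factor s, the mean AIS
#' over all loci and cross-group pairs: corrected value =
#' (mean AIS of the pair - s) / (1 - s).
#'
#' @inheritParams kinshipWAIS
#' @return a [KinshipMatrix-class] tagged "BNO".
#' @export
kinshipBNO <- function(gm, unrelatedGroups) {
  out <- .kinshipGroupCorrected(gm, unrelatedGroups, perLocus = FALSE)
  KinshipMatrix(out, "BNO", as.character(unrelatedGroups))
}

#' Loiselle coancestry
#'
#' Correlation-type estimator on individual allele frequencies
#' x in \{0, 0.5, 1\}: f_ij = [sum_l sum_a (x_ila - p_la)(x_jla - p_la) +
#' sum_l sum_a p_la (1 - p_la) / (n_l - 1)] / [sum_l sum_a p_la (1 - p_la)],
#' with p_la the sample frequency and n_l the number of genotyped
#' individuals at locus l. The second numerator term is the small-sample
#' bias correction that centres unrelated pairs at zero. For a pair with
#' missing calls the sums run over their shared loci.
#'
#' @param gm a [GenotypePanel-class].
#' @return a [KinshipMatrix-class] tagged "LOI".
#' @export
kinshipLoiselle <- function(gm) {
  n <- nInd(gm)
  counts <- .alleleCounts(gm)
  num <- den <- bias <- matrix(0, n, n)
  any_poly <- FALSE
  for (l in names(counts)) {
    cnt <- counts[[l]]
    ok <- !is.na(cnt[, 1])
    n_l <- sum(ok)
    if (n_l < 2) next
    p <- colSums(cnt[ok, , drop = FALSE]) / (2 * n_l)
    den_l <- sum(p * (1 - p))
    if (den_l <= 0) next
    any_poly <- TRUE
    x <- cnt / 2
    xc <- sweep(x, 2, p)
    xc[!ok, ] <- 0
    num <- num + tcrossprod(xc)
    m <- outer(ok, ok)
    den <- den + den_l * m
    bias <- bias + den_l / (n_l - 1) * m
  }
  if (!any_poly) stop("all loci monomorphic: Loiselle denominator undefined")
  out <- (num + bias) / den
  dimnames(out) <- list(indIds(gm), indIds(gm))
  KinshipMatrix(out, "LOI")
}

# ---- pairwise IBD likelihood machinery (MLE kinship + relationship calls) --

.freqList <- function(gm, freqs = NULL) {
  if (is.null(freqs)) freqs <- alleleFrequencies(gm)
  out <- split(freqs, freqs$locus_id)
  # only exact zeros are floored (a genotyped allele absent from the
  # frequency table's reference panel); observed frequencies stay exact so
  # likelihood ties remain exact
  lapply(out, function(d)
    setNames(ifelse(d$freq <= 0 | is.na(d$freq), 1e-12, d$freq), d$allele))
}

# SNP genotype-pair probabilities given 0/1/2 IBD alleles, as L x 9 matrices
# indexed by 3*gi + gj + 1 with gi, gj the alt-allele counts
.snpPairProbTables <- function(p_alt) {
  q <- 1 - p_alt; p <- p_alt
  pg <- cbind(q^2, 2 * p * q, p^2)                  # P(G), G = 0,1,2
  f_ref <- cbind(q, p, 0)                           # f(G | shared = ref)
  f_alt <- cbind(0, q, p)                           # f(G | shared = alt)
  L <- length(p)
  P0 <- P1 <- P2 <- matrix(0, L, 9)
  for (gi in 0:2) for (gj in 0:2) {
    k <- 3 * gi + gj + 1
    P0[, k] <- pg[, gi + 1] * pg[, gj + 1]
    P1[, k] <- q * f_ref[, gi + 1] * f_ref[, gj + 1] +
               p * f_alt[, gi + 1] * f_alt[, gj + 1]
    P2[, k] <- (gi == gj) * pg[, gi + 1]
  }
  list(P0 = P0, P1 = P1, P2 = P2)
}

# SSR genotype-pair probabilities for one pair at one locus; genotypes as
# canonical allele pairs (a <= b), freqs a named vector
.ssrPairProb <- function(a1, b1, a2, b2, f) {
  pa1 <- f[as.character(a1)]; pb1 <- f[as.character(b1)]
  pa2 <- f[as.character(a2)]; pb2 <- f[as.character(b2)]
  pg1 <- if (a1 == b1) pa1^2 else 2 * pa1 * pb1
  pg2 <- if (a2 == b2) pa2^2 else 2 * pa2 * pb2
  fcond <- function(a, b, s, pa, pb) {
    if (a == b) (s == a) * pa
    else (s == a) * pb + (s == b) * pa
  }
  shared <- unique(c(a1, b1, a2, b2))
  p1 <- 0
  for (s in shared)
    p1 <- p1 + f[as.character(s)] *
      fcond(a1, b1, s, pa1, pb1) * fcond(a2, b2, s, pa2, pb2)
  p2 <- if (a1 == a2 && b1 == b2) pg1 else 0
  c(unname(pg1 * pg2), unname(p1), unname(p2))
}

# build P0/P1/P2/mask matrices (L x nPairs) for the given pair index matrix
.pairLikelihoodComponents <- function(gm, pairs, freqs = NULL) {
  fl <- .freqList(gm, freqs)
  np <- nrow(pairs)
  snp_ids <- colnames(gm@snp)
  ssr_ids <- colnames(gm@ssrA)
  L <- length(snp_ids) + length(ssr_ids)
  P0 <- P1 <- P2 <- matrix(1, L, np)
  mask <- matrix(FALSE, L, np)
  if (length(snp_ids)) {
    missing_f <- setdiff(snp_ids, names(fl))
    if (length(missing_f))
      stop("freqs must cover all loci; missing: ", missing_f[1])
    p_alt <- vapply(fl[snp_ids], function(f)
      if ("alt" %in% names(f)) f[["alt"]] else f[[2]], numeric(1))
    tabs <- .snpPairProbTables(p_alt)
    gi <- round(2 * t(gm@snp[pairs[, 1], snp_ids, drop = FALSE])) # L x np
    gj <- round(2 * t(gm@snp[pairs[, 2], snp_ids, drop = FALSE]))
    ok <- !is.na(gi) & !is.na(gj)
    idx <- 3 * gi + gj + 1
    rowsel <- row(idx)
    sel <- cbind(rowsel[ok], idx[ok])
    for (nm in c("P0", "P1", "P2")) {
      tmp <- matrix(1, length(snp_ids), np)
      tmp[ok] <- tabs[[nm]][sel]
      if (nm == "P0") P0[seq_along(snp_ids), ] <- tmp
      if (nm == "P1") P1[seq_along(snp_ids), ] <- tmp
      if (nm == "P2") P2[seq_along(snp_ids), ] <- tmp
    }
    mask[seq_along(snp_ids), ] <- ok
  }
  if (length(ssr_ids)) {
    off <- length(snp_ids)
    for (li in seq_along(ssr_ids)) {
      l <- ssr_ids[li]
      f <- fl[[l]]
      if (is.null(f)) stop("freqs must cover all loci; missing: ", l)
      a <- gm@ssrA[, l]; b <- gm@ssrB[, l]
      for (k in seq_len(np)) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (is.na(a[i]) || is.na(a[j])) next
        pr <- .ssrPairProb(a[i], b[i], a[j], b[j], f)
        P0[off + li, k] <- pr[1]
        P1[off + li, k] <- pr[2]
        P2[off + li, k] <- pr[3]
        mask[off + li, k] <- TRUE
      }
    }
  }
  list(P0 = P0, P1 = P1, P2 = P2, mask = mask)
}

#' Maximum-likelihood coancestry from IBD-coefficient estimation
#'
#' For each pair, the probability vector (k0, k1, k2) of sharing 0/1/2
#' alleles identical by descent is estimated by maximising the product over
#' loci of sum_m k_m P(G_i, G_j | m IBD alleles, allele freqs), using an EM
#' iteration on the mixture weights from the start (1/3, 1/3, 1/3), at most
#' \code{maxIter} iterations and log-likelihood tolerance \code{tol}.
#' Coancestry = k1/4 + k2/2. No genotyping-error parameter is included.
#'
#' @param gm a [GenotypePanel-class].
#' @param freqs allele-frequency table as from [alleleFrequencies()]
#'   (default: computed from \code{gm}); must cover every locus.
#' @param pairs optional 2-column matrix of individual indices or ids; the
#'   default is all unordered pairs plus the diagonal.
#' @param maxIter,tol EM controls.
#' @return a [KinshipMatrix-class] tagged "MLE" when \code{pairs} is NULL,
#'   otherwise a data.frame (ind1, ind2, k0, k1, k2, kinship, logLik,
#'   converged, n_loci).
#' @export
kinshipMLE <- function(gm, freqs = NULL, pairs = NULL, maxIter = 200,
                       tol = 1e-6) {
  full <- is.null(pairs)
  n <- nInd(gm)
  if (full) {
    idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    pairs <- idx[, c(2, 1)] # row <= col
    colnames(pairs) <- NULL
  } else {
    pairs <- as.matrix(pairs)
    if (is.character(pairs))
      pairs <- matrix(match(pairs, indIds(gm)), ncol = 2)
  }
  est <- .emIBD(gm, pairs, freqs, maxIter, tol)
  if (!all(est$converged))
    warning(sprintf("%d pairs did not reach the EM tolerance; last iterate kept",
                    sum(!est$converged)))
  if (full) {
    K <- matrix(0, n, n, dimnames = list(indIds(gm), indIds(gm)))
    kin <- est$k[2, ] / 4 + est$k[3, ] / 2
    K[pairs] <- kin
    K[pairs[, c(2, 1)]] <- kin
    return(KinshipMatrix(K, "MLE"))
  }
  data.frame(ind1 = indIds(gm)[pairs[, 1]], ind2 = indIds(gm)[pairs[, 2]],
             k0 = est$k[1, ], k1 = est$k[2, ], k2 = est$k[3, ],
             kinship = est$k[2, ] / 4 + est$k[3, ] / 2,
             logLik = est$logLik, converged = est$converged,
             n_loci = est$n_loci)
}

# EM over mixture weights, vectorised across pairs (chunked to bound memory)
.emIBD <- function(gm, pairs, freqs, maxIter, tol) {
  np <- nrow(pairs)
  kout <- matrix(NA_real_, 3, np)
  ll <- rep(NA_real_, np)
  conv <- rep(FALSE, np)
  nloci <- rep(0L, np)
  chunk <- max(1L, floor(2e7 / max(1L, nLoci(gm))))
  for (s in seq(1, np, by = chunk)) {
    jj <- s:min(np, s + chunk - 1)
    comp <- .pairLikelihoodComponents(gm, pairs[jj, , drop = FALSE], freqs)
    m <- comp$mask
    nl <- colSums(m)
    k <- matrix(1 / 3, 3, length(jj))
    prev <- rep(-Inf, length(jj))
    done <- nl == 0
    for (it in seq_len(maxIter)) {
      D <- k[1, ][col(comp$P0)] * comp$P0 +
           k[2, ][col(comp$P0)] * comp$P1 +
           k[3, ][col(comp$P0)] * comp$P2
      D <- pmax(D, 1e-300)
      cur <- colSums(log(D) * m)
      w0 <- colSums(k[1, ][col(D)] * comp$P0 / D * m)
      w1 <- colSums(k[2, ][col(D)] * comp$P1 / D * m)
      w2 <- colSums(k[3, ][col(D)] * comp$P2 / D * m)
      tot <- pmax(w0 + w1 + w2, 1e-300)
      k <- rbind(w0, w1, w2) / rep(tot, each = 3)
      newly <- !done & abs(cur - prev) < tol
      done <- done | newly
      prev <- cur
      if (all(done)) break
    }
    # boundary polish: the log-likelihood is concave in k, but EM approaches
    # vertex optima only geometrically; if a simplex vertex beats the final
    # iterate, the vertex is the maximiser
    for (v in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      Dv <- v[1] * comp$P0 + v[2] * comp$P1 + v[3] * comp$P2
      llv <- colSums(log(pmax(Dv, 1e-300)) * m)
      take <- llv > prev
      if (any(take)) {
        k[, take] <- v
        prev[take] <- llv[take]
        done <- done | take
      }
    }
    kout[, jj] <- k
    ll[jj] <- prev
    conv[jj] <- done
    nloci[jj] <- nl
  }
  list(k = kout, logLik = ll, converged = conv, n_loci = nloci)
}

RELATIONSHIP_K <- list(U = c(1, 0, 0), HS = c(0.5, 0.5, 0),
                       FS = c(0.25, 0.5, 0.25), PO = c(0, 1, 0))

#' Classify pairwise relationships by fixed-IBD likelihood
#'
#' Evaluates the pair log-likelihood at the canonical IBD-coefficient
#' vectors U = (1,0,0), HS = (0.5,0.5,0), FS = (0.25,0.5,0.25) and
#' PO = (0,1,0); the best category attains the maximal log-likelihood, with
#' ties resolved in favour of U, then HS. A pair with an opposite-homozygote
#' locus has PO log-likelihood -Inf (Mendelian exclusion). Pairs are flagged
#' first-degree when the best category is PO or FS.
#'
#' @param gm a [GenotypePanel-class].
#' @param pairs 2-column matrix of individual ids or indices; default all
#'   unordered pairs (diagonal excluded).
#' @param freqs allele-frequency table covering every locus (default from
#'   \code{gm}).
#' @param minLoci soft minimum of informative loci per pair (warning below).
#' @return data.frame with per-category log-likelihoods, \code{best},
#'   \code{first_degree} and \code{n_loci}.
#' @export
classifyRelationship <- function(gm, pairs = NULL, freqs = NULL,
                                 minLoci = 20) {
  n <- nInd(gm)
  if (is.null(pairs)) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- idx[, c(2, 1)]
    colnames(pairs) <- NULL
  } else {
    pairs <- as.matrix(pairs)
    if (is.character(pairs))
      pairs <- matrix(match(pairs, indIds(gm)), ncol = 2)
  }
  comp <- .pairLikelihoodComponents(gm, pairs, freqs)
  m <- comp$mask
  nl <- colSums(m)
  if (any(nl < minLoci))
    warning(sprintf("%d pairs have fewer than %d informative loci",
                    sum(nl < minLoci), minLoci))
  ll <- sapply(RELATIONSHIP_K, function(k) {
    D <- k[1] * comp$P0 + k[2] * comp$P1 + k[3] * comp$P2
    lg <- log(D)
    lg[!m] <- 0
    colSums(lg)
  })
  ll <- matrix(ll, ncol = 4, dimnames = list(NULL, names(RELATIONSHIP_K)))
  # ties resolved in column order U, HS, FS, PO (with a small absolute
  # tolerance so exact ties survive floating-point noise)
  best <- colnames(ll)[apply(ll, 1, function(v)
    which(v >= max(v) - 1e-9)[1])]
  data.frame(ind1 = indIds(gm)[pairs[, 1]], ind2 = indIds(gm)[pairs[, 2]],
             ll_U = ll[, "U"], ll_HS = ll[, "HS"], ll_FS = ll[, "FS"],
             ll_PO = ll[, "PO"], best = best,
             first_degree = best %in% c("PO", "FS"), n_loci = nl)
}

#' Select the kinship estimator minimising inter-chromosomal corrected LD
#'
#' True LD between loci on different chromosomes is expected null, so the
#' estimator whose kinship correction yields the lowest mean r2_V over
#' inter-chromosomal locus pairs (MAF >= \code{minMaf}) removes relatedness
#' signal best. Ties are broken by tag order AIS < WAIS2 < WAIS4 < BNO <
#' LOI < MLE < identity.
#'
#' @param gm a [GenotypePanel-class] (at least 2 chromosomes among the
#'   selected loci).
#' @param kinships list of candidate [KinshipMatrix-class] objects.
#' @param loci optional locus selection (ids); default all SNPs.
#' @param S optional [StructureMatrix-class]: when given, r2_VS is the
#'   criterion instead of r2_V.
#' @param minMaf MAF filter (default 0.05).
#' @return the winning estimator tag; per-candidate means are in
#'   \code{attr(, "mean_interchrom_ld")}.
#' @export
selectEstimatorByInterchromLD <- function(gm, kinships, loci = NULL, S = NULL,
                                          minMaf = 0.05) {
  tags <- vapply(kinships, estimatorTag, character(1))
  means <- setNames(numeric(length(kinships)), tags)
  for (i in seq_along(kinships)) {
    ld <- pairwiseLD(gm, loci = loci, K = kinships[[i]], S = S,
                     minMaf = minMaf)
    inter <- is.na(ld$dist_bp)
    if (!any(inter)) stop("need loci on at least 2 chromosomes")
    col <- if (is.null(S)) "r2_v" else "r2_vs"
    means[i] <- mean(ld[[col]][inter], na.rm = TRUE)
  }
  ord <- order(means, match(tags, KINSHIP_TAGS))
  out <- tags[ord[1]]
  attr(out, "mean_interchrom_ld") <- means
  out
}
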