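#' @include kinship.R
NULL

# make a covariance candidate usable as a model covariance: truncate
# negative (corrected-estimator) entries at 0, then ensure Cholesky
# factorisability: a single ridge retry (eps = 1e-6 * mean diagonal) for
# near-PSD matrices, then eigenvalue clipping -- group-corrected estimators
# truncated at 0 are routinely indefinite, which a small ridge cannot repair
.preparePD <- function(K, label = "kinship matrix") {
  K <- as.matrix(K)
  K[K < 0] <- 0
  K <- (K + t(K)) / 2
  ok <- tryCatch({ chol(K); TRUE }, error = function(e) FALSE)
  if (ok) return(K)
  Kr <- K + diag(1e-6 * mean(diag(K)), nrow(K))
  ok <- tryCatch({ chol(Kr); TRUE }, error = function(e) FALSE)
  if (ok) return(Kr)
  e <- eigen(K, symmetric = TRUE)
  # floor at 1% of the leading eigenvalue: bounds the whitening condition
  # number at 100 so estimated near-null directions are not blown up
  floorval <- 1e-2 * max(abs(e$values))
  if (floorval <= 0)
    stop(sprintf("the %s is identically zero", label))
  lam <- pmax(e$values, floorval)
  K <- e$vectors %*% (lam * t(e$vectors))
  (K + t(K)) / 2
}

# whitening operator: z = L^-1 v with K = L L'
.whiten <- function(K, M, label = "kinship matrix") {
  R <- chol(.preparePD(K, label))
  forwardsolve(t(R), M)
}

#' Classical and kinship/structure-corrected LD between two loci
#'
#' With neither K nor S, the classical r2: squared Pearson correlation of
#' the dosage vectors. With K, the kinship-corrected r2_V: both dosages and
#' the intercept are whitened by the inverse lower Cholesky factor of K,
#' the whitened dosages are residualised on the whitened intercept, and
#' r2_V is the squared correlation of the residuals. With K and S, r2_VS:
#' the covariates are the whitened intercept plus the whitened structure
#' columns (the last membership column is dropped for identifiability).
#' Computation is on pairwise-complete individuals.
#'
#' @param x,y dosage vectors (same individuals; at least 3 pairwise-complete
#'   values required).
#' @param K optional [KinshipMatrix-class] (or plain matrix) over the same
#'   individuals.
#' @param S optional [StructureMatrix-class] over the same individuals
#'   (requires K).
#' @return squared correlation in [0, 1]; NA with a warning when a residual
#'   has zero variance.
#' @export
r2Corrected <- function(x, y, K = NULL, S = NULL) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  idx <- which(!is.na(x) & !is.na(y))
  if (length(idx) < 3) stop("need at least 3 pairwise-complete individuals")
  x <- x[idx]; y <- y[idx]
  if (is.null(K)) {
    if (!is.null(S)) stop("S requires K")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance dosage; r2 undefined")
      return(NA_real_)
    }
    return(stats::cor(x, y)^2)
  }
  Km <- as.matrix(K)[idx, idx, drop = FALSE]
  covars <- matrix(1, length(idx), 1)
  if (!is.null(S)) {
    Sm <- as.matrix(S)[idx, , drop = FALSE]
    if (ncol(Sm) > 1) covars <- cbind(covars, Sm[, -ncol(Sm), drop = FALSE])
  }
  W <- .whiten(Km, cbind(covars, x, y))
  nc <- ncol(covars)
  res <- stats::lm.fit(W[, seq_len(nc), drop = FALSE],
                       W[, nc + c(1, 2)])$residuals
  # the GLS correlation: residuals are already orthogonal to the whitened
  # intercept, so no further centring is applied
  s1 <- sum(res[, 1]^2); s2 <- sum(res[, 2]^2)
  if (s1 == 0 || s2 == 0) {
    warning("zero-variance whitened residual; corrected r2 undefined")
    return(NA_real_)
  }
  min(sum(res[, 1] * res[, 2])^2 / (s1 * s2), 1)
}

#' Pairwise LD table over a locus selection
#'
#' All unordered pairs among the selected SNP loci passing the MAF filter.
#' Distances come from the locus map; pairs on different chromosomes get
#' \code{dist_bp = NA}. Classical r2 is always reported; r2_V when K is
#' given; r2_VS when K and S are given. When the dosage block is complete
#' (no missing calls) all loci are whitened and residualised once; with
#' missing data each pair is computed on its pairwise-complete individuals.
#'
#' @param gm a [GenotypePanel-class].
#' @param loci locus ids (or indices into the map); default all SNPs.
#' @param K optional [KinshipMatrix-class].
#' @param S optional [StructureMatrix-class] (requires K).
#' @param minMaf minor-allele-frequency filter (default 0.05; the paper
#'   workflow's "MAF > 5 %" convention is a >= threshold here, matching
#'   [filterLoci()]).
#' @return data.frame with locus_a, locus_b, chrom_a, chrom_b, pos_a,
#'   pos_b, dist_bp, r2, r2_v, r2_vs, n_used.
#' @export
pairwiseLD <- function(gm, loci = NULL, K = NULL, S = NULL, minMaf = 0.05) {
  loc <- gm@loci
  if (is.null(loci)) loci <- loc$locus_id[loc$locus_type == "snp"]
  if (!is.character(loci)) loci <- loc$locus_id[loci]
  loci <- loci[loc$locus_type[match(loci, loc$locus_id)] == "snp"]
  maf <- .locusMaf(gm)[loci]
  loci <- loci[!is.na(maf) & maf >= minMaf]
  if (length(loci) < 2) stop("fewer than 2 loci after the MAF filter")
  X <- gm@snp[, loci, drop = FALSE]
  info <- loc[match(loci, loc$locus_id), ]
  pr <- which(upper.tri(diag(length(loci))), arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), c(1, 2), drop = FALSE]
  a <- pr[, 1]; b <- pr[, 2]
  same <- info$chrom[a] == info$chrom[b]
  out <- data.frame(
    locus_a = loci[a], locus_b = loci[b],
    chrom_a = info$chrom[a], chrom_b = info$chrom[b],
    pos_a = info$pos_bp[a], pos_b = info$pos_bp[b],
    dist_bp = ifelse(same, abs(info$pos_bp[a] - info$pos_bp[b]), NA_integer_),
    r2 = NA_real_, r2_v = NA_real_, r2_vs = NA_real_,
    n_used = NA_integer_)
  complete <- !anyNA(X)
  if (complete) {
    C <- stats::cor(X)^2
    out$r2 <- C[pr]
    out$n_used <- nrow(X)
    if (!is.null(K)) {
      glsR2 <- function(res) {
        C <- crossprod(res)
        d <- diag(C)
        pmin(C^2 / outer(d, d), 1)
      }
      covars <- matrix(1, nrow(X), 1)
      W <- .whiten(as.matrix(K), cbind(covars, X))
      res <- stats::lm.fit(W[, 1, drop = FALSE], W[, -1, drop = FALSE])$residuals
      out$r2_v <- glsR2(res)[pr]
      if (!is.null(S)) {
        Sm <- as.matrix(S)
        if (ncol(Sm) > 1) covars <- cbind(covars, Sm[, -ncol(Sm), drop = FALSE])
        W <- .whiten(as.matrix(K), cbind(covars, X))
        res <- stats::lm.fit(W[, seq_len(ncol(covars)), drop = FALSE],
                             W[, -seq_len(ncol(covars)), drop = FALSE])$residuals
        out$r2_vs <- glsR2(res)[pr]
      }
    }
  } else {
    for (k in seq_len(nrow(pr))) {
      xi <- X[, a[k]]; yi <- X[, b[k]]
      idx <- !is.na(xi) & !is.na(yi)
      out$n_used[k] <- sum(idx)
      out$r2[k] <- tryCatch(r2Corrected(xi, yi), error = function(e) NA_real_)
      if (!is.null(K)) {
        out$r2_v[k] <- tryCatch(r2Corrected(xi, yi, K),
                                error = function(e) NA_real_)
        if (!is.null(S))
          out$r2_vs[k] <- tryCatch(r2Corrected(xi, yi, K, S),
                                   error = function(e) NA_real_)
      }
    }
  }
  out
}

#' Sliding-window mean LD along a region
#'
#' Windows of \code{windowBp} anchored at their start coordinate step by
#' \code{stepBp} across the span of the table's loci; a pair belongs to a
#' window iff both loci lie inside it, and windows with fewer than
#' \code{minPairs} pairs report NA.
#'
#' @param ld an LD table from [pairwiseLD()] restricted to one chromosome.
#' @param windowBp window width in bp (> 0).
#' @param stepBp step in bp (> 0).
#' @param minPairs minimum pair count per window (default 10).
#' @param ldColumn which LD column to average ("r2", "r2_v", "r2_vs").
#' @return data.frame with window_start, window_end, n_pairs, mean_ld.
#' @export
slidingWindowLD <- function(ld, windowBp, stepBp, minPairs = 10,
                            ldColumn = "r2") {
  if (windowBp <= 0) stop("windowBp must be > 0")
  if (stepBp <= 0) stop("stepBp must be > 0")
  if (length(unique(c(ld$chrom_a, ld$chrom_b))) > 1)
    stop("ld table must be restricted to one chromosome")
  v <- ld[[ldColumn]]
  lo <- pmin(ld$pos_a, ld$pos_b)
  hi <- pmax(ld$pos_a, ld$pos_b)
  span0 <- min(lo); span1 <- max(hi)
  starts <- seq(span0, span1, by = stepBp)
  res <- lapply(starts, function(s) {
    inw <- lo >= s & hi <= s + windowBp - 1
    n <- sum(inw & !is.na(v))
    data.frame(window_start = s, window_end = s + windowBp - 1,
               n_pairs = n,
               mean_ld = if (n >= minPairs) mean(v[inw], na.rm = TRUE) else NA_real_)
  })
  do.call(rbind, res)
}
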