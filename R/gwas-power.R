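#' @include ld-decay.R
NULL

#' Effective number of independent tests (Li-Ji)
#'
#' From the eigenvalues lambda_i of the locus-locus Pearson correlation
#' matrix (pairwise-complete; undefined correlations set to 0 with a
#' warning): Meff = sum_i [ I(|lambda_i| >= 1) + (|lambda_i| -
#' floor(|lambda_i|)) ]. Zero-variance loci are dropped with a warning
#' before the eigendecomposition.
#'
#' @param gm a [GenotypePanel-class].
#' @param loci locus ids or indices (default: all SNPs).
#' @return the effective test count (numeric scalar, 1 <= Meff <= M).
#' @export
meffLiJi <- function(gm, loci = NULL) {
  loc <- gm@loci
  if (is.null(loci)) loci <- loc$locus_id[loc$locus_type == "snp"]
  if (!is.character(loci)) loci <- loc$locus_id[loci]
  X <- gm@snp[, loci, drop = FALSE]
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  if (any(is.na(v) | v == 0)) {
    warning(sprintf("dropping %d zero-variance loci before eigendecomposition",
                    sum(is.na(v) | v == 0)))
    X <- X[, !is.na(v) & v > 0, drop = FALSE]
  }
  if (ncol(X) < 1) stop("no polymorphic loci")
  if (ncol(X) == 1) return(1)
  C <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  if (anyNA(C)) {
    warning("correlations with no complete pairs set to 0")
    C[is.na(C)] <- 0
  }
  lam <- abs(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  sum((lam >= 1) + (lam - floor(lam)))
}

# V^-1-based Wald ingredients for design [1, x]; returns list(varBeta, w)
# with w the row of (X'V^-1X)^-1 X'V^-1 that estimates beta
.waldOperator <- function(x, K, h2, qEffect) {
  N <- length(x)
  s2_gl <- (1 - qEffect) * h2
  s2_e <- 1 - h2
  V <- s2_gl * .preparePD(as.matrix(K)) + diag(s2_e, N)
  Vi <- chol2inv(chol(.preparePD(V, "model covariance V")))
  X <- cbind(1, x)
  XtVi <- crossprod(X, Vi)
  B <- solve(XtVi %*% X)
  list(varBeta = B[2, 2], w = (B %*% XtVi)[2, ])
}

#' Analytic power of the mixed-model Wald test at a locus
#'
#' Under Y = 1 mu + x beta + U + E with known variance components on a unit
#' total-variance scale (sigma2_e = 1 - h2, residual polygenic sigma2_gl =
#' (1 - qEffect) h2, V = sigma2_gl K + sigma2_e I) and beta calibrated so
#' the locus explains qEffect of the additive genetic variance
#' (beta = sqrt(qEffect h2 / Var_emp(x))), the Wald statistic for beta is
#' noncentral chi-square with 1 df and noncentrality lambda =
#' beta^2 / var(beta_hat), var(beta_hat) the locus entry of
#' (X' V^-1 X)^-1. Power is the upper-tail probability beyond the central
#' chi-square(1) quantile at the spec's per-test alpha.
#'
#' @param x dosage vector of the tested locus (missing values mean-imputed;
#'   monomorphic loci yield NA with a warning).
#' @param K a [KinshipMatrix-class] (truncated at 0 and ridged before
#'   inversion).
#' @param spec a [powerSpec()].
#' @return power in [alpha, 1].
#' @export
powerAtLocus <- function(x, K, spec) {
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  vx <- stats::var(x)
  if (is.na(vx) || vx == 0) {
    warning("monomorphic locus: power undefined")
    return(NA_real_)
  }
  beta <- sqrt(spec@qEffect * spec@h2 / vx)
  op <- .waldOperator(x, K, spec@h2, spec@qEffect)
  lambda <- beta^2 / op$varBeta
  q <- stats::qchisq(1 - spec@alpha, df = 1)
  stats::pchisq(q, df = 1, ncp = lambda, lower.tail = FALSE)
}

#' Power at a marker linked to the causal locus
#'
#' The power at a linked marker is the power at the causal locus multiplied
#' by the (corrected) LD between marker and causal locus.
#'
#' @param powerCausal power at the causal locus, in [0, 1] (or percent; the
#'   scale is preserved).
#' @param r2vs corrected LD between marker and causal locus, in [0, 1].
#' @return \code{powerCausal * r2vs}.
#' @export
powerAtMarker <- function(powerCausal, r2vs) {
  stopifnot(all(r2vs >= 0), all(r2vs <= 1))
  powerCausal * r2vs
}

#' Analytic power over a locus selection and a scenario grid
#'
#' Full factorial per-locus analytic power over heritabilities x locus
#' effects, at per-test threshold fwer / Meff with Meff computed on the same
#' locus selection (after the MAF filter). Deterministic.
#'
#' @param gm a [GenotypePanel-class].
#' @param K a [KinshipMatrix-class].
#' @param loci locus ids (default all SNPs).
#' @param h2List heritability grid.
#' @param qList locus-effect grid (fraction of additive genetic variance).
#' @param fwer family-wise error rate (default 0.05).
#' @param mafMin MAF filter (default 0.05).
#' @return data.frame (locus x scenario rows) with power, MAF, region and
#'   the kinship tag; mean power per region x scenario in
#'   \code{attr(, "summary")}; Meff in \code{attr(, "meff")}.
#' @export
powerGrid <- function(gm, K, loci = NULL, h2List = c(0.3, 0.5, 0.7, 0.9),
                      qList = c(0.05, 0.1, 0.25), fwer = 0.05,
                      mafMin = 0.05) {
  loc <- gm@loci
  if (is.null(loci)) loci <- loc$locus_id[loc$locus_type == "snp"]
  if (!is.character(loci)) loci <- loc$locus_id[loci]
  maf <- .locusMaf(gm)[loci]
  loci <- loci[!is.na(maf) & maf >= mafMin]
  if (!length(loci)) stop("no loci after the MAF filter")
  meff <- meffLiJi(gm, loci)
  tag <- estimatorTag(K)
  maf <- .locusMaf(gm)[loci]
  region <- loc$region[match(loci, loc$locus_id)]
  rows <- list()
  for (h2 in h2List) for (q in qList) {
    sp <- powerSpec(h2, q, fwer = fwer, meff = meff, kinshipTag = tag)
    # the Wald operator depends on the scenario, not the locus dosages'
    # identity, so V^-1 is factorised once per cell
    N <- nInd(gm)
    s2_gl <- (1 - q) * h2
    V <- s2_gl * .preparePD(as.matrix(K)) + diag(1 - h2, N)
    Vi <- chol2inv(chol(.preparePD(V, "model covariance V")))
    Vi1 <- Vi %*% rep(1, N)
    s11 <- sum(Vi1)
    pw <- vapply(loci, function(l) {
      x <- gm@snp[, l]
      if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
      vx <- stats::var(x)
      if (vx == 0) return(NA_real_)
      Vix <- Vi %*% x
      xtvx <- drop(crossprod(x, Vix))
      xtv1 <- drop(crossprod(x, Vi1))
      varB <- 1 / (xtvx - xtv1^2 / s11)
      lambda <- (q * h2 / vx) / varB
      stats::pchisq(stats::qchisq(1 - sp@alpha, 1), 1, ncp = lambda,
                    lower.tail = FALSE)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = loci, h2 = h2, q_effect = q, power = unname(pw),
      maf = unname(maf), region = region, kinship = tag)
  }
  out <- do.call(rbind, rows)
  sm <- stats::aggregate(power ~ h2 + q_effect + region, out, mean)
  attr(out, "summary") <- sm
  attr(out, "meff") <- meff
  out
}

#' Empirical power of the mixed-model Wald test by simulation
#'
#' Simulates phenotypes under the same model as [simulatePhenotype()]
#' (known variance components) and counts rejections of the Wald test for
#' the causal locus at the given threshold. The analytic
#' [powerAtLocus()] value is the large-replicate limit of this rate.
#'
#' @param gm a [GenotypePanel-class].
#' @param K a [KinshipMatrix-class] (used both to simulate and to test).
#' @param h2,qEffect scenario as in [powerSpec()].
#' @param causal SNP locus_id of the causal locus.
#' @param alpha per-test threshold.
#' @param nRep number of phenotype replicates.
#' @param seed integer seed.
#' @return rejection rate in [0, 1].
#' @export
empiricalPower <- function(gm, K, h2, qEffect, causal, alpha, nRep = 2000,
                           seed = 1) {
  x <- gm@snp[, causal]
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  vx <- stats::var(x)
  if (vx == 0) stop(sprintf("causal locus '%s' is monomorphic", causal))
  set.seed(seed)
  N <- length(x)
  beta <- sqrt(qEffect * h2 / vx)
  s2_gl <- (1 - qEffect) * h2
  s2_e <- 1 - h2
  Kp <- .preparePD(as.matrix(K))
  R <- chol(Kp)
  op <- .waldOperator(x, K, h2, qEffect)
  qcrit <- stats::qchisq(1 - alpha, 1)
  U <- if (s2_gl > 0) sqrt(s2_gl) * t(R) %*%
         matrix(stats::rnorm(N * nRep), N) else matrix(0, N, nRep)
  E <- matrix(stats::rnorm(N * nRep, sd = sqrt(s2_e)), N)
  Y <- beta * x + U + E
  bhat <- drop(crossprod(op$w, Y))
  mean(bhat^2 / op$varBeta > qcrit)
}
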