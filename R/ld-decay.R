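#' @include corrected-ld.R
NULL

#' Hill-Weir expected r2 as a function of recombination and sample size
#'
#' E[r2] = [(10 + C) / ((2 + C)(11 + C))] *
#' [1 + ((3 + C)(12 + 12C + C^2)) / (n (2 + C)(11 + C))], where C is the
#' population recombination parameter between the two loci (here rho * d for
#' physical distance d) and n the sample size. Drift-recombination
#' equilibrium expectation with the first-order sample-size correction.
#'
#' @param C nonnegative recombination parameter (vectorised).
#' @param n sample size (>= 2).
#' @return expected r2.
#' @export
hillWeirExpectation <- function(C, n) {
  stopifnot(all(C >= 0), n >= 2)
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Predicted LD of a decay fit at given distances
#'
#' @param fit a [DecayFit-class].
#' @param d physical distances in bp.
#' @return expected r2 at each distance.
#' @export
predictLD <- function(fit, d) hillWeirExpectation(fit@rho * d, fit@n)

#' Fit the Hill-Weir decay curve to a pairwise LD table
#'
#' Least squares in rho: minimises sum over pairs of
#' (observed - E[r2](rho d, n))^2, over rho in [1e-12, 1] per bp, with 8
#' log-spaced multi-starts of a bounded quasi-Newton search on log(rho);
#' the best optimum is kept. Deterministic. Pairs without a finite distance
#' (inter-chromosomal) or LD value are dropped; at least 10 are required.
#'
#' @param ld LD table from [pairwiseLD()].
#' @param n sample size entering the expectation (number of genotyped
#'   individuals behind the LD table).
#' @param ldColumn which LD estimate to fit ("r2", "r2_v", "r2_vs").
#' @return a [DecayFit-class].
#' @export
fitHillWeir <- function(ld, n, ldColumn = "r2") {
  d <- ld$dist_bp
  r <- ld[[ldColumn]]
  ok <- is.finite(d) & is.finite(r)
  d <- as.numeric(d[ok]); r <- r[ok]
  if (length(d) < 10) stop("need at least 10 pairs with finite distance and LD")
  if (all(d == 0)) stop("all distances are zero; rho is not identifiable")
  ss <- function(lrho) sum((r - hillWeirExpectation(exp(lrho) * d, n))^2)
  starts <- log(10^seq(-11, -0.5, length.out = 8))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, ss, method = "L-BFGS-B",
                   lower = log(1e-12), upper = 0),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("Hill-Weir fit failed to converge from any start")
  new("DecayFit", rho = exp(best$par), n = as.numeric(n),
      nPairs = length(d), residSS = best$value, ldColumn = ldColumn)
}

#' LD extent: distance at which the fitted curve crosses a threshold
#'
#' The unique root of E[r2](rho d, n) = threshold, found by bisection to
#' relative tolerance 1e-6. The threshold must lie strictly below the curve
#' value at d = 0 (the curve decreases from there towards 0).
#'
#' @param fit a [DecayFit-class].
#' @param threshold LD threshold (default 0.2, the conventional extent
#'   definition).
#' @return distance in bp.
#' @export
ldExtent <- function(fit, threshold = 0.2) {
  at0 <- hillWeirExpectation(0, fit@n)
  if (threshold >= at0)
    stop(sprintf("curve never attains threshold from above (value at 0 = %.4f)", at0))
  if (threshold <= 0) stop("threshold must be positive")
  if (fit@rho <= 0) stop("rho = 0: the fitted curve never decays")
  f <- function(d) predictLD(fit, d) - threshold
  hi <- 1
  while (f(hi) > 0 && hi < 1e15) hi <- hi * 10
  if (f(hi) > 0) stop("threshold not reached within 1e15 bp")
  lo <- 0
  while ((hi - lo) > 1e-6 * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Genome-wide marker count required to reach a target LD with any locus
#'
#' With markers equally spaced every 2 d* bp, any causal position lies
#' within d* = the LD extent at \code{targetR2} of its nearest marker, so
#' the expected LD with the nearest marker is at least the target:
#' count = ceiling(genome size / (2 d*)).
#'
#' @param fit a [DecayFit-class].
#' @param genomeSizeBp genome size in bp.
#' @param targetR2 target expected r2 at the nearest marker.
#' @return integer marker count.
#' @export
markersRequired <- function(fit, genomeSizeBp, targetR2) {
  dstar <- ldExtent(fit, targetR2)
  as.integer(ceiling(genomeSizeBp / (2 * dstar)))
}
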