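#' @import methods
NULL

DOSAGE_LEVELS <- c(0, 0.5, 1)

#' GenotypePanel: diploid genotypes for a germplasm panel
#'
#' Container for individuals-by-loci diploid genotype calls at biallelic SNPs
#' (additive dosage coded 0 for one homozygote, 0.5 for heterozygotes, 1 for
#' the other homozygote) and multiallelic SSR-like loci (unordered integer
#' allele pairs), together with the locus map (chromosome, 1-based bp
#' position, region label) and individual metadata (subgroup, founder flag).
#'
#' @slot individuals data.frame with columns \code{ind_id}, \code{subgroup},
#'   \code{founder}.
#' @slot loci data.frame with columns \code{locus_id}, \code{chrom},
#'   \code{pos_bp}, \code{locus_type} ("snp" or "ssr"), \code{region}.
#' @slot snp numeric matrix (individuals x SNP loci) with values in
#'   \{0, 0.5, 1, NA\}.
#' @slot ssrA,ssrB integer matrices (individuals x SSR loci) holding the
#'   unordered allele pair in canonical order (\code{ssrA <= ssrB}); NA in
#'   both marks a missing call.
#'
#' @seealso [GenotypePanel()] for the constructor, [readGenotypes()].
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  representation(
    individuals = "data.frame",
    loci        = "data.frame",
    snp         = "matrix",
    ssrA        = "matrix",
    ssrB        = "matrix"
  )
)

setValidity("GenotypePanel", function(object) {
  msgs <- character()
  ind <- object@individuals
  loc <- object@loci
  need_ind <- c("ind_id", "subgroup", "founder")
  need_loc <- c("locus_id", "chrom", "pos_bp", "locus_type", "region")
  if (!all(need_ind %in% names(ind)))
    msgs <- c(msgs, "individuals must have columns ind_id, subgroup, founder")
  if (!all(need_loc %in% names(loc)))
    msgs <- c(msgs, "loci must have columns locus_id, chrom, pos_bp, locus_type, region")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(ind$ind_id))
    msgs <- c(msgs, "duplicated ind_id")
  if (anyDuplicated(loc$locus_id))
    msgs <- c(msgs, "duplicated locus_id")
  if (any(loc$pos_bp < 1, na.rm = TRUE))
    msgs <- c(msgs, "pos_bp must be >= 1")
  if (!all(loc$locus_type %in% c("snp", "ssr")))
    msgs <- c(msgs, "locus_type must be 'snp' or 'ssr'")
  n <- nrow(ind)
  snp_ids <- loc$locus_id[loc$locus_type == "snp"]
  ssr_ids <- loc$locus_id[loc$locus_type == "ssr"]
  if (nrow(object@snp) != n || ncol(object@snp) != length(snp_ids))
    msgs <- c(msgs, "snp matrix dimensions do not match metadata")
  if (length(snp_ids) && !identical(colnames(object@snp), snp_ids))
    msgs <- c(msgs, "snp matrix column names must equal the snp locus_ids in map order")
  if (nrow(object@ssrA) != n || ncol(object@ssrA) != length(ssr_ids) ||
      !identical(dim(object@ssrA), dim(object@ssrB)))
    msgs <- c(msgs, "ssr matrices dimensions do not match metadata")
  else if (length(ssr_ids) && !identical(colnames(object@ssrA), ssr_ids))
    msgs <- c(msgs, "ssr matrix column names must equal the ssr locus_ids in map order")
  bad <- object@snp[!is.na(object@snp)]
  if (length(bad) && !all(bad %in% DOSAGE_LEVELS))
    msgs <- c(msgs, "snp dosages must be in {0, 0.5, 1, NA}")
  if (length(object@ssrA)) {
    if (!identical(is.na(object@ssrA), is.na(object@ssrB)))
      msgs <- c(msgs, "ssr allele pair must be missing jointly")
    if (any(object@ssrA > object@ssrB, na.rm = TRUE))
      msgs <- c(msgs, "ssr allele pairs must be stored in canonical order (a1 <= a2)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypePanel
#'
#' @param snp numeric matrix of SNP dosages (individuals x loci, values in
#'   \{0, 0.5, 1, NA\}); may have zero columns.
#' @param ssr optional list with integer matrices \code{a1}, \code{a2}
#'   (individuals x SSR loci); pairs are stored unordered (canonicalised).
#' @param loci data.frame locus map (\code{locus_id}, \code{chrom},
#'   \code{pos_bp}, \code{locus_type}, \code{region}); defaults are built
#'   from the matrix column names when omitted.
#' @param individuals data.frame with \code{ind_id} and optional
#'   \code{subgroup}, \code{founder}.
#' @return A validated [GenotypePanel-class] object.
#' @export
GenotypePanel <- function(snp = NULL, ssr = NULL, loci = NULL,
                          individuals = NULL) {
  if (is.null(snp) && is.null(ssr))
    stop("at least one of 'snp' or 'ssr' is required")
  n <- if (!is.null(snp)) nrow(snp) else nrow(ssr$a1)
  if (is.null(individuals)) {
    ids <- if (!is.null(snp) && !is.null(rownames(snp))) rownames(snp)
           else if (!is.null(ssr) && !is.null(rownames(ssr$a1))) rownames(ssr$a1)
           else sprintf("ind%03d", seq_len(n))
    individuals <- data.frame(ind_id = ids)
  }
  if (is.null(individuals$subgroup)) individuals$subgroup <- NA_character_
  if (is.null(individuals$founder))  individuals$founder  <- FALSE
  individuals$ind_id <- as.character(individuals$ind_id)
  individuals$subgroup <- as.character(individuals$subgroup)

  if (is.null(snp)) snp <- matrix(numeric(0), nrow = n, ncol = 0)
  storage.mode(snp) <- "double"
  if (is.null(colnames(snp)) && ncol(snp))
    colnames(snp) <- sprintf("snp%04d", seq_len(ncol(snp)))
  if (is.null(ssr)) {
    ssrA <- ssrB <- matrix(integer(0), nrow = n, ncol = 0)
  } else {
    ssrA <- ssr$a1; ssrB <- ssr$a2
    storage.mode(ssrA) <- "integer"; storage.mode(ssrB) <- "integer"
    if (is.null(colnames(ssrA)) && ncol(ssrA))
      colnames(ssrA) <- colnames(ssrB) <- sprintf("ssr%02d", seq_len(ncol(ssrA)))
    # canonical unordered storage; a pair is missing as a whole
    miss <- is.na(ssrA) | is.na(ssrB)
    ssrA[miss] <- NA_integer_; ssrB[miss] <- NA_integer_
    swap <- !miss & ssrA > ssrB
    if (any(swap)) {
      tmp <- ssrA[swap]; ssrA[swap] <- ssrB[swap]; ssrB[swap] <- tmp
    }
    colnames(ssrB) <- colnames(ssrA)
  }
  rownames(snp) <- rownames(ssrA) <- rownames(ssrB) <- individuals$ind_id

  if (is.null(loci)) {
    loci <- data.frame(
      locus_id   = c(colnames(snp), colnames(ssrA)),
      chrom      = "chrUn",
      pos_bp     = seq_len(ncol(snp) + ncol(ssrA)),
      locus_type = rep(c("snp", "ssr"), c(ncol(snp), ncol(ssrA))),
      region     = NA_character_
    )
  }
  loci$locus_id <- as.character(loci$locus_id)
  loci$chrom <- as.character(loci$chrom)
  loci$pos_bp <- as.integer(loci$pos_bp)
  if (is.null(loci$region)) loci$region <- NA_character_
  # order matrices to map order
  snp  <- snp[, loci$locus_id[loci$locus_type == "snp"], drop = FALSE]
  ssrA <- ssrA[, loci$locus_id[loci$locus_type == "ssr"], drop = FALSE]
  ssrB <- ssrB[, loci$locus_id[loci$locus_type == "ssr"], drop = FALSE]
  rownames(individuals) <- NULL
  rownames(loci) <- NULL
  new("GenotypePanel", individuals = individuals, loci = loci,
      snp = snp, ssrA = ssrA, ssrB = ssrB)
}

#' StructureMatrix: ancestry membership coefficients
#'
#' An N x K matrix of membership probabilities (rows sum to 1) as produced by
#' model-based clustering of genotypes; row names are individual ids and
#' column names the group labels.
#'
#' @exportClass StructureMatrix
setClass("StructureMatrix", contains = "matrix")

setValidity("StructureMatrix", function(object) {
  q <- object@.Data
  if (any(q < -1e-8 | q > 1 + 1e-8))
    return("membership coefficients must lie in [0, 1]")
  if (any(abs(rowSums(q) - 1) > 1e-8))
    return("membership rows must sum to 1 (tolerance 1e-8)")
  if (is.null(colnames(q))) return("group labels (colnames) required")
  TRUE
})

#' Construct a StructureMatrix
#'
#' @param Q numeric matrix of membership coefficients; rows individuals,
#'   columns groups. Rows must sum to 1 within 1e-8.
#' @param groupLabels optional column labels.
#' @return A validated [StructureMatrix-class].
#' @export
structureMatrix <- function(Q, groupLabels = colnames(Q)) {
  Q <- as.matrix(Q)
  if (is.null(groupLabels)) groupLabels <- sprintf("G%d", seq_len(ncol(Q)))
  colnames(Q) <- groupLabels
  new("StructureMatrix", Q)
}

KINSHIP_TAGS <- c("AIS", "WAIS2", "WAIS4", "BNO", "LOI", "MLE", "identity")

#' KinshipMatrix: marker-based coancestry estimates
#'
#' A symmetric N x N matrix of pairwise coancestry values tagged with the
#' estimator that produced it and, for group-corrected estimators, the
#' unrelated-group partition assumed. Corrected estimators (WAIS, BNO, LOI,
#' MLE-adjusted) can legitimately hold negative entries; they are truncated
#' at zero only when the matrix enters a model covariance (see
#' [r2Corrected()], [powerAtLocus()]).
#'
#' @slot estimator one of "AIS", "WAIS2", "WAIS4", "BNO", "LOI", "MLE",
#'   "identity".
#' @slot groups character vector of per-individual unrelated-group labels
#'   used for correction (length 0 for uncorrected estimators).
#' @exportClass KinshipMatrix
setClass("KinshipMatrix", contains = "matrix",
  representation(estimator = "character", groups = "character"))

setValidity("KinshipMatrix", function(object) {
  k <- object@.Data
  if (nrow(k) != ncol(k)) return("kinship matrix must be square")
  if (max(abs(k - t(k)), na.rm = TRUE) > 1e-8)
    return("kinship matrix must be symmetric")
  if (!object@estimator %in% KINSHIP_TAGS)
    return(sprintf("unknown estimator tag '%s'", object@estimator))
  TRUE
})

#' Construct a KinshipMatrix
#'
#' @param values symmetric numeric matrix with individual ids as dimnames.
#' @param estimator estimator tag.
#' @param groups per-individual unrelated-group labels (corrected estimators
#'   only).
#' @return A validated [KinshipMatrix-class].
#' @export
KinshipMatrix <- function(values, estimator, groups = character()) {
  new("KinshipMatrix", as.matrix(values), estimator = estimator,
      groups = as.character(groups))
}

#' DecayFit: fitted Hill-Weir LD decay curve
#'
#' Holds the per-bp decay parameter rho of the Hill-Weir expected-r2 model
#' fitted to a pairwise LD table, together with the sample size entering the
#' expectation and fit diagnostics.
#'
#' @slot rho per-bp decay rate (population recombination per bp), >= 0.
#' @slot n sample size used in the small-sample term of the expectation.
#' @slot nPairs number of locus pairs used in the fit.
#' @slot residSS residual sum of squares at the optimum.
#' @slot ldColumn which LD estimate was fitted ("r2", "r2_v" or "r2_vs").
#' @exportClass DecayFit
setClass("DecayFit",
  representation(rho = "numeric", n = "numeric", nPairs = "integer",
                 residSS = "numeric", ldColumn = "character"))

setValidity("DecayFit", function(object) {
  if (object@rho < 0) return("rho must be >= 0")
  if (object@n < 2) return("n must be >= 2")
  TRUE
})

#' PanelSelection: result of the association-panel design workflow
#'
#' @slot selection named list (one element per subgroup) of selected
#'   individual ids, in selection order.
#' @slot founders ids retained mandatorily.
#' @slot log data.frame iteration log (subgroup, iteration, removed,
#'   replacement, flagged).
#' @slot targetSize target size per subgroup.
#' @exportClass PanelSelection
setClass("PanelSelection",
  representation(selection = "list", founders = "character",
                 log = "data.frame", targetSize = "integer"))

#' PowerSpec: scenario for analytic association power
#'
#' @slot h2 broad-sense heritability of the simulated trait on a unit
#'   total-variance scale.
#' @slot qEffect fraction of additive genetic variance explained by the
#'   tested locus.
#' @slot fwer family-wise error rate.
#' @slot meff effective number of independent tests (Li-Ji).
#' @slot alpha per-test threshold, fwer / meff.
#' @slot kinshipTag estimator tag of the kinship matrix used.
#' @exportClass PowerSpec
setClass("PowerSpec",
  representation(h2 = "numeric", qEffect = "numeric", fwer = "numeric",
                 meff = "numeric", alpha = "numeric", kinshipTag = "character"))

setValidity("PowerSpec", function(object) {
  if (object@h2 < 0 || object@h2 > 1) return("h2 must be in [0, 1]")
  if (object@qEffect < 0 || object@qEffect > 1) return("qEffect must be in [0, 1]")
  if (object@alpha <= 0 || object@alpha > object@fwer)
    return("alpha must satisfy 0 < alpha <= fwer")
  TRUE
})

#' Construct a PowerSpec
#'
#' @param h2 heritability in [0, 1].
#' @param qEffect fraction of additive genetic variance due to the locus.
#' @param fwer family-wise error rate (default 0.05).
#' @param meff effective number of independent tests; the per-test threshold
#'   is \code{fwer / meff}.
#' @param kinshipTag estimator tag carried for bookkeeping.
#' @return A validated [PowerSpec-class].
#' @export
powerSpec <- function(h2, qEffect, fwer = 0.05, meff = 1, kinshipTag = "AIS") {
  new("PowerSpec", h2 = h2, qEffect = qEffect, fwer = fwer, meff = meff,
      alpha = fwer / meff, kinshipTag = kinshipTag)
}
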