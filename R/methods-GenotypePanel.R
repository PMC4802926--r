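#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname nInd
#' @export
setMethod("nInd", "GenotypePanel", function(x) nrow(x@individuals))

#' @rdname nInd
#' @export
setMethod("nLoci", "GenotypePanel", function(x) nrow(x@loci))

#' @rdname indIds
#' @export
setMethod("indIds", "GenotypePanel", function(x) x@individuals$ind_id)

#' @rdname indIds
#' @export
setMethod("indIds", "KinshipMatrix", function(x) rownames(x@.Data))

#' @rdname indInfo
#' @export
setMethod("indInfo", "GenotypePanel", function(x) x@individuals)

#' @rdname locusInfo
#' @export
setMethod("locusInfo", "GenotypePanel", function(x) x@loci)

#' @rdname snpDosage
#' @export
setMethod("snpDosage", "GenotypePanel", function(x) x@snp)

#' @rdname ssrAlleles
#' @export
setMethod("ssrAlleles", "GenotypePanel", function(x) list(a1 = x@ssrA, a2 = x@ssrB))

#' @rdname estimatorTag
#' @export
setMethod("estimatorTag", "KinshipMatrix", function(x) x@estimator)

#' Strip a KinshipMatrix or StructureMatrix to its base matrix
#'
#' @param x the object.
#' @param ... ignored.
#' @return plain numeric matrix with dimnames.
#' @export
setMethod("as.matrix", "KinshipMatrix", function(x, ...) x@.Data)

#' @rdname as.matrix-KinshipMatrix-method
#' @export
setMethod("as.matrix", "StructureMatrix", function(x, ...) x@.Data)

#' @rdname panelIds
#' @export
setMethod("panelIds", "PanelSelection", function(x) unlist(x@selection, use.names = FALSE))

#' Subset a GenotypePanel
#'
#' \code{x[i, j]} keeps individuals \code{i} and loci \code{j} (indices,
#' logicals, or ids into the individual/locus tables); order is preserved as
#' given.
#'
#' @param x a [GenotypePanel-class].
#' @param i individual selector.
#' @param j locus selector (positions in the locus map).
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nInd(x))
  if (missing(j)) j <- seq_len(nLoci(x))
  if (is.character(i)) i <- match(i, x@individuals$ind_id)
  if (is.character(j)) j <- match(j, x@loci$locus_id)
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  if (anyNA(i)) stop("unknown individual id in subset")
  if (anyNA(j)) stop("unknown locus id in subset")
  ind <- x@individuals[i, , drop = FALSE]
  loc <- x@loci[j, , drop = FALSE]
  snp_keep <- loc$locus_id[loc$locus_type == "snp"]
  ssr_keep <- loc$locus_id[loc$locus_type == "ssr"]
  rownames(ind) <- NULL; rownames(loc) <- NULL
  new("GenotypePanel",
      individuals = ind, loci = loc,
      snp  = x@snp[i, snp_keep, drop = FALSE],
      ssrA = x@ssrA[i, ssr_keep, drop = FALSE],
      ssrB = x@ssrB[i, ssr_keep, drop = FALSE])
})

setMethod("show", "GenotypePanel", function(object) {
  nsnp <- sum(object@loci$locus_type == "snp")
  nssr <- sum(object@loci$locus_type == "ssr")
  cat(sprintf("GenotypePanel: %d individuals, %d loci (%d SNP, %d SSR)\n",
              nInd(object), nLoci(object), nsnp, nssr))
  grp <- table(object@individuals$subgroup, useNA = "ifany")
  if (length(grp))
    cat("  subgroups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  miss <- missingFraction(object)
  cat(sprintf("  overall missingness: %.3f\n", mean(miss)))
})

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix (%s): %d individuals\n",
              object@estimator, nrow(object@.Data)))
  off <- object@.Data[upper.tri(object@.Data)]
  cat(sprintf("  off-diagonal mean %.4f, range [%.4f, %.4f]\n",
              mean(off, na.rm = TRUE), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE)))
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("Hill-Weir decay fit (%s): rho = %.3g /bp, n = %d, %d pairs, RSS = %.4g\n",
              object@ldColumn, object@rho, as.integer(object@n),
              object@nPairs, object@residSS))
})

setMethod("show", "PanelSelection", function(object) {
  sizes <- vapply(object@selection, length, integer(1))
  cat(sprintf("PanelSelection: %d subgroups x target %d\n",
              length(object@selection), object@targetSize))
  cat("  sizes:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  cat(sprintf("  founders retained: %d; pruning iterations logged: %d\n",
              length(object@founders), nrow(object@log)))
})

#' Per-locus missing-call fraction
#'
#' @param gm a [GenotypePanel-class].
#' @param by "locus" (default) or "individual".
#' @return named numeric vector of missing fractions.
#' @export
missingFraction <- function(gm, by = c("locus", "individual")) {
  by <- match.arg(by)
  m_snp <- is.na(gm@snp)
  m_ssr <- is.na(gm@ssrA)
  if (by == "locus") {
    out <- c(colMeans(m_snp), colMeans(m_ssr))
    out[gm@loci$locus_id]
  } else {
    tot <- ncol(m_snp) + ncol(m_ssr)
    if (tot == 0) return(setNames(rep(0, nInd(gm)), indIds(gm)))
    setNames((rowSums(m_snp) + rowSums(m_ssr)) / tot, indIds(gm))
  }
}
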