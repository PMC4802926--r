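#' @include AllClasses.R
NULL

#' Number of individuals / loci in a panel
#'
#' @param x a [GenotypePanel-class].
#' @return integer count.
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname nInd
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Individual ids of a panel or kinship matrix
#' @param x a [GenotypePanel-class] or [KinshipMatrix-class].
#' @return character vector.
#' @export
setGeneric("indIds", function(x) standardGeneric("indIds"))

#' Individual metadata table
#' @param x a [GenotypePanel-class].
#' @return data.frame with ind_id, subgroup, founder.
#' @export
setGeneric("indInfo", function(x) standardGeneric("indInfo"))

#' Locus map table
#' @param x a [GenotypePanel-class].
#' @return data.frame with locus_id, chrom, pos_bp, locus_type, region.
#' @export
setGeneric("locusInfo", function(x) standardGeneric("locusInfo"))

#' SNP dosage matrix
#' @param x a [GenotypePanel-class].
#' @return numeric matrix (individuals x SNP loci), values in {0, 0.5, 1, NA}.
#' @export
setGeneric("snpDosage", function(x) standardGeneric("snpDosage"))

#' SSR allele-pair matrices
#' @param x a [GenotypePanel-class].
#' @return list with integer matrices \code{a1}, \code{a2} (canonical order).
#' @export
setGeneric("ssrAlleles", function(x) standardGeneric("ssrAlleles"))

#' Estimator tag of a kinship matrix
#' @param x a [KinshipMatrix-class].
#' @return character scalar.
#' @export
setGeneric("estimatorTag", function(x) standardGeneric("estimatorTag"))

#' Selected panel ids
#' @param x a [PanelSelection-class].
#' @return character vector (all subgroups pooled) or use
#'   \code{selection(x)} per subgroup.
#' @export
setGeneric("panelIds", function(x) standardGeneric("panelIds"))
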