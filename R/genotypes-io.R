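#' @include AllClasses.R methods-GenotypePanel.R
NULL

# dosage <-> GT coding used by the VCF reader/writer. Phase is ignored
# (unphased analysis throughout); multiallelic records are rejected.
.gtToDosage <- function(gt, line_no = NA_integer_) {
  gt <- sub(":.*$", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_real_, length(gt))
  out[gt %in% c("0/0")] <- 0
  out[gt %in% c("0/1", "1/0")] <- 0.5
  out[gt %in% c("1/1")] <- 1
  known <- gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".", "./0", "0/.")
  if (!all(known))
    stop(sprintf("unsupported GT code '%s'%s", gt[!known][1],
                 if (is.na(line_no)) "" else sprintf(" at VCF record %d", line_no)))
  out[gt %in% c("./0", "0/.")] <- NA_real_
  out
}

#' Read genotypes from VCF, dosage table, or SSR table
#'
#' Three dialects are supported. \code{vcf}: VCFv4.x, GT field only,
#' biallelic records (multiallelic ALT is an error); hom-ref maps to dosage
#' 0, heterozygote to 0.5, hom-alt to 1, \code{./.} to missing; phase is
#' ignored. \code{dosage_table}: tab-delimited, first column \code{ind_id},
#' one column per SNP with values 0 / 0.5 / 1 / NA. \code{ssr_table}:
#' tab-delimited, first column \code{ind_id} then two columns per locus named
#' \code{<locus>_a1}, \code{<locus>_a2} holding integer allele labels; blank
#' or NA marks a missing call.
#'
#' @param path file to read.
#' @param fmt one of "vcf", "dosage_table", "ssr_table".
#' @param loci optional locus map data.frame to attach (see
#'   [readLocusMap()]); for VCF the map is taken from the file itself.
#' @return A [GenotypePanel-class].
#' @export
readGenotypes <- function(path, fmt = c("vcf", "dosage_table", "ssr_table"),
                          loci = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path))
  if (fmt == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop classes
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi))
      stop(sprintf("multiallelic VCF record at %s:%s; only biallelic SNPs are supported",
                   fix[multi, "CHROM"][1], fix[multi, "POS"][1]))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), rownames(gt)))
    for (k in seq_len(nrow(gt))) {
      g <- gt[k, ]
      g[is.na(g)] <- "./."
      dos[, k] <- .gtToDosage(g, k)
    }
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix[, "CHROM"], fix[, "POS"])[is.na(ids) | ids == "."]
    if (anyDuplicated(ids)) stop("duplicated locus_id in VCF")
    colnames(dos) <- ids
    map <- data.frame(locus_id = ids, chrom = fix[, "CHROM"],
                      pos_bp = as.integer(fix[, "POS"]),
                      locus_type = "snp", region = NA_character_)
    return(GenotypePanel(snp = dos, loci = map))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "ind_id") stop("first column must be 'ind_id'")
  if (anyDuplicated(tab$ind_id)) stop("duplicated ind_id")
  ids <- as.character(tab$ind_id)
  if (fmt == "dosage_table") {
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    bad <- m[!is.na(m)]
    if (length(bad) && !all(bad %in% DOSAGE_LEVELS)) {
      culprit <- which(!is.na(m) & !(m %in% DOSAGE_LEVELS), arr.ind = TRUE)[1, ]
      stop(sprintf("invalid dosage %s for individual '%s' at locus '%s'",
                   format(m[culprit[1], culprit[2]]), ids[culprit[1]],
                   colnames(m)[culprit[2]]))
    }
    gp <- GenotypePanel(snp = m, loci = loci,
                        individuals = data.frame(ind_id = ids))
  } else {
    cn <- names(tab)[-1]
    base <- unique(sub("_a[12]$", "", cn))
    need <- c(paste0(base, "_a1"), paste0(base, "_a2"))
    if (!all(need %in% cn))
      stop("ssr_table needs '<locus>_a1' and '<locus>_a2' columns for every locus")
    a1 <- as.matrix(tab[, paste0(base, "_a1"), drop = FALSE])
    a2 <- as.matrix(tab[, paste0(base, "_a2"), drop = FALSE])
    storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
    colnames(a1) <- colnames(a2) <- base
    rownames(a1) <- rownames(a2) <- ids
    if (is.null(loci))
      loci <- data.frame(locus_id = base, chrom = "chrUn",
                         pos_bp = seq_along(base), locus_type = "ssr",
                         region = NA_character_)
    gp <- GenotypePanel(ssr = list(a1 = a1, a2 = a2), loci = loci,
                        individuals = data.frame(ind_id = ids))
  }
  gp
}

#' Write genotypes in the formats of [readGenotypes()]
#'
#' @param gm a [GenotypePanel-class].
#' @param path output file.
#' @param fmt one of "vcf", "dosage_table", "ssr_table". The VCF writer emits
#'   placeholder REF/ALT alleles (A/C): only the dosage information is
#'   carried, and a write/read round-trip is lossless for it.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(gm, path, fmt = c("vcf", "dosage_table", "ssr_table")) {
  fmt <- match.arg(fmt)
  loc <- gm@loci
  if (fmt == "vcf") {
    snp_loc <- loc[loc$locus_type == "snp", , drop = FALSE]
    gtmap <- c(`0` = "0/0", `0.5` = "0/1", `1` = "1/1")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", indIds(gm)), collapse = "\t")), con)
    for (k in seq_len(nrow(snp_loc))) {
      x <- gm@snp[, snp_loc$locus_id[k]]
      gt <- ifelse(is.na(x), "./.", gtmap[as.character(x)])
      writeLines(paste(c(snp_loc$chrom[k], snp_loc$pos_bp[k],
                         snp_loc$locus_id[k], "A", "C", ".", ".", ".", "GT", gt),
                       collapse = "\t"), con)
    }
  } else if (fmt == "dosage_table") {
    df <- data.frame(ind_id = indIds(gm), gm@snp, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    a <- gm@ssrA; b <- gm@ssrB
    df <- data.frame(ind_id = indIds(gm), check.names = FALSE)
    for (l in colnames(a)) {
      df[[paste0(l, "_a1")]] <- a[, l]
      df[[paste0(l, "_a2")]] <- b[, l]
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a locus map
#'
#' Tab-delimited with header: \code{locus_id}, \code{chrom}, \code{pos_bp}
#' (1-based), \code{locus_type} ("snp"/"ssr"), optional \code{region}.
#'
#' @param path file to read.
#' @return data.frame usable as the \code{loci} slot.
#' @export
readLocusMap <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("locus_id", "chrom", "pos_bp", "locus_type")
  if (!all(need %in% names(m)))
    stop("locus map needs columns locus_id, chrom, pos_bp, locus_type")
  if (anyDuplicated(m$locus_id)) stop("duplicated locus_id in map")
  if (is.null(m$region)) m$region <- NA_character_
  m$pos_bp <- as.integer(m$pos_bp)
  if (any(m$pos_bp < 1)) stop("pos_bp must be >= 1")
  m
}

#' Read individual metadata (subgroup, founder flag, membership matrix)
#'
#' Tab-delimited with header: \code{ind_id}, optional \code{subgroup},
#' \code{founder}, and membership columns \code{q1..qK}.
#'
#' @param path file to read.
#' @return list with \code{info} (data.frame) and \code{Q} (a
#'   [StructureMatrix-class] or NULL when no q columns are present).
#' @export
readIndividualMeta <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (is.null(m$ind_id)) stop("metadata needs an ind_id column")
  qcols <- grep("^q[0-9]+$", names(m), value = TRUE)
  Q <- NULL
  if (length(qcols)) {
    Q <- as.matrix(m[, qcols, drop = FALSE])
    rownames(Q) <- m$ind_id
    Q <- structureMatrix(Q, qcols)
  }
  info <- data.frame(ind_id = as.character(m$ind_id),
                     subgroup = if (is.null(m$subgroup)) NA_character_ else as.character(m$subgroup),
                     founder = if (is.null(m$founder)) FALSE else as.logical(m$founder))
  list(info = info, Q = Q)
}

# per-locus minor allele frequency: for SNPs min(p, 1-p) of the alt dosage
# mean; for multiallelic SSRs the frequency of the second most common allele
# (always <= 0.5).
.locusMaf <- function(gm) {
  loc <- gm@loci
  out <- setNames(rep(NA_real_, nrow(loc)), loc$locus_id)
  if (ncol(gm@snp)) {
    p <- colMeans(gm@snp, na.rm = TRUE)
    out[colnames(gm@snp)] <- pmin(p, 1 - p)
  }
  for (l in colnames(gm@ssrA)) {
    alle <- c(gm@ssrA[, l], gm@ssrB[, l])
    alle <- alle[!is.na(alle)]
    if (!length(alle)) next
    f <- sort(table(alle) / length(alle), decreasing = TRUE)
    out[l] <- if (length(f) >= 2) unname(f[2]) else 0
  }
  out
}

#' Filter loci by missingness and minor allele frequency
#'
#' Keeps loci whose missing-call fraction is at most \code{maxMissing} and
#' whose MAF is at least \code{minMaf} (SNPs: folded alt-allele frequency;
#' SSRs: frequency of the second most common allele). Survivor order is
#' preserved; individuals are untouched. An all-missing locus has undefined
#' MAF and is dropped whenever \code{minMaf > 0}.
#'
#' @param gm a [GenotypePanel-class].
#' @param maxMissing maximum tolerated per-locus missing fraction in [0, 1].
#' @param minMaf minimum minor allele frequency in [0, 0.5].
#' @return the filtered [GenotypePanel-class].
#' @export
filterLoci <- function(gm, maxMissing = 1, minMaf = 0) {
  stopifnot(maxMissing >= 0, maxMissing <= 1, minMaf >= 0, minMaf <= 0.5)
  miss <- missingFraction(gm, "locus")
  maf <- .locusMaf(gm)
  keep <- miss <= maxMissing & (minMaf == 0 | (!is.na(maf) & maf >= minMaf))
  if (!any(keep)) warning("no loci survive the filter")
  gm[, which(keep)]
}

#' Filter individuals by missingness and structure membership
#'
#' Keeps individuals whose missing fraction is at most \code{maxMissing} and
#' whose maximum membership coefficient is at least \code{minMembership};
#' surviving individuals are assigned \code{subgroup = } the argmax
#' membership label.
#'
#' @param gm a [GenotypePanel-class].
#' @param q a [StructureMatrix-class] with rows aligned to \code{gm}'s
#'   individuals (by rowname when present, else by position).
#' @param maxMissing maximum missing fraction in [0, 1].
#' @param minMembership minimum top membership in [0, 1].
#' @return the filtered [GenotypePanel-class] with updated subgroups.
#' @export
filterIndividuals <- function(gm, q, maxMissing = 1, minMembership = 0) {
  Q <- as.matrix(q)
  if (nrow(Q) != nInd(gm))
    stop("membership matrix rows do not match panel individuals")
  if (!is.null(rownames(Q))) {
    if (!setequal(rownames(Q), indIds(gm)))
      stop("membership matrix rownames do not match panel individuals")
    Q <- Q[indIds(gm), , drop = FALSE]
  }
  top <- apply(Q, 1, max)
  lab <- colnames(Q)[apply(Q, 1, which.max)]
  miss <- missingFraction(gm, "individual")
  keep <- which(top >= minMembership & miss <= maxMissing)
  out <- gm[keep, ]
  out@individuals$subgroup <- lab[keep]
  out
}
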