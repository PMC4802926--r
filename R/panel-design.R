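#' @include gwas-power.R
NULL

#' Simple-matching dissimilarity between individuals
#'
#' Per locus, the similarity of two unordered genotypes is the fraction of
#' alleles that can be matched between them (1, 0.5 or 0 for diploids);
#' dissimilarity is 1 minus the mean similarity over loci non-missing in
#' both individuals. Symmetric, zero diagonal.
#'
#' @param gm a [GenotypePanel-class].
#' @return N x N labelled dissimilarity matrix (NA with a warning for pairs
#'   sharing no genotyped locus).
#' @export
simpleMatchingDissimilarity <- function(gm) {
  n <- nInd(gm)
  simsum <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (l in colnames(gm@snp)) {
    a <- 2 * gm@snp[, l] # alt-allele counts 0/1/2
    s <- (outer(a, a, pmin) + outer(2 - a, 2 - a, pmin)) / 2
    ok <- !is.na(s)
    s[!ok] <- 0
    simsum <- simsum + s
    cnt <- cnt + ok
  }
  if (ncol(gm@ssrA)) for (l in colnames(gm@ssrA)) {
    a <- gm@ssrA[, l]; b <- gm@ssrB[, l]
    m1 <- outer(a, a, "==") + outer(b, b, "==")
    m2 <- outer(a, b, "==") + outer(b, a, "==")
    s <- pmax(m1, m2) / 2
    ok <- !is.na(s)
    s[!ok] <- 0
    simsum <- simsum + s
    cnt <- cnt + ok
  }
  if (any(cnt == 0))
    warning("some pairs share no genotyped locus; dissimilarity set to NA")
  out <- 1 - simsum / cnt
  dimnames(out) <- list(indIds(gm), indIds(gm))
  out
}

#' Greedy maximin diversity subsample
#'
#' Starts from the mandatory set (or, when empty, the globally most distant
#' pair) and repeatedly adds the candidate whose minimum dissimilarity to
#' the current selection is largest, until \code{m} are selected. Ties are
#' broken by the lexically smallest id, making the procedure deterministic
#' and invariant to candidate input order.
#'
#' @param D complete dissimilarity matrix with candidate ids as dimnames.
#' @param m target selection size.
#' @param mandatory ids that must be included (seeded first).
#' @return character vector of selected ids, in selection order.
#' @export
maximinSubsample <- function(D, m, mandatory = character()) {
  ids <- rownames(D)
  if (m > length(ids))
    stop(sprintf("m = %d exceeds the %d candidates", m, length(ids)))
  if (!all(mandatory %in% ids)) stop("mandatory ids must be candidates")
  if (m < length(mandatory)) stop("m smaller than the mandatory set")
  if (length(mandatory) == 0) {
    if (m == 1) return(sort(ids)[1])
    # globally most distant pair; ties -> lexically smallest pair
    ord <- order(rownames(D))
    Ds <- D[ord, ord]
    best <- which(Ds == max(Ds, na.rm = TRUE), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    sel <- sort(rownames(Ds)[best[1, ]])
  } else {
    sel <- mandatory
  }
  remaining <- setdiff(ids, sel)
  mind <- if (length(remaining))
    apply(D[remaining, sel, drop = FALSE], 1, min) else numeric(0)
  while (length(sel) < m) {
    if (!length(remaining)) stop("candidates exhausted")
    pick <- sort(names(mind)[mind == max(mind)])[1]
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
    mind <- pmin(mind[remaining], D[remaining, pick])
  }
  sel
}

#' Design a structure-balanced, low-relatedness association panel
#'
#' Per subgroup: candidates are the individuals assigned to the subgroup
#' (argmax membership) with top membership at least \code{membershipMin}
#' (founders of the subgroup are kept regardless); the selection is seeded
#' with the founders and filled to \code{subgroupSize} by greedy maximin on
#' the simple-matching dissimilarity. All within-panel pairs are then
#' classified with [classifyRelationship()]; while any first-degree pair
#' remains, the non-founder member with the larger mean alikeness-in-state
#' kinship to the rest of the panel is removed (founders are never removed;
#' a pair of two founders is flagged and kept) and the affected subgroup is
#' refilled by maximin from its remaining candidates. Every iteration is
#' logged. Terminates because each iteration permanently removes a
#' candidate or accepts a founder pair.
#'
#' @param gm the collection [GenotypePanel-class].
#' @param q a [StructureMatrix-class] over the collection.
#' @param founders ids retained mandatorily.
#' @param subgroupSize target panel size per subgroup.
#' @param freqs allele frequencies for the relationship classifier (default:
#'   computed on the whole collection).
#' @param membershipMin membership threshold (default 0.8).
#' @param subgroups which membership columns get a panel (default all).
#' @return a [PanelSelection-class].
#' @export
designPanel <- function(gm, q, founders = character(), subgroupSize,
                        freqs = NULL, membershipMin = 0.8,
                        subgroups = colnames(q)) {
  Q <- as.matrix(q)
  if (nrow(Q) != nInd(gm)) stop("membership matrix rows must match individuals")
  ids <- indIds(gm)
  if (!is.null(rownames(Q))) Q <- Q[ids, , drop = FALSE]
  if (is.null(freqs)) freqs <- alleleFrequencies(gm)
  assigned <- colnames(Q)[apply(Q, 1, which.max)]
  top <- apply(Q, 1, max)
  D <- simpleMatchingDissimilarity(gm)
  Kais <- as.matrix(kinshipAIS(gm))
  dimnames(Kais) <- dimnames(D)

  candidates <- lapply(subgroups, function(g)
    ids[assigned == g & (top >= membershipMin | (ids %in% founders))])
  names(candidates) <- subgroups
  founders_by_g <- lapply(subgroups, function(g)
    intersect(founders, candidates[[g]]))
  names(founders_by_g) <- subgroups

  selection <- list()
  for (g in subgroups) {
    if (length(candidates[[g]]) < subgroupSize)
      stop(sprintf("subgroup %s: only %d candidates for target size %d",
                   g, length(candidates[[g]]), subgroupSize))
    selection[[g]] <- maximinSubsample(
      D[candidates[[g]], candidates[[g]], drop = FALSE],
      subgroupSize, founders_by_g[[g]])
  }

  log <- data.frame(subgroup = character(), iteration = integer(),
                    removed = character(), replacement = character(),
                    flagged = character())
  accepted <- character() # founder-founder pairs kept despite the flag
  it <- 0L
  repeat {
    it <- it + 1L
    pool <- unlist(selection, use.names = FALSE)
    sub <- gm[pool, ]
    calls <- classifyRelationship(sub, freqs = freqs)
    flagged <- calls[calls$first_degree, , drop = FALSE]
    if (nrow(flagged)) {
      key <- paste(pmin(flagged$ind1, flagged$ind2),
                   pmax(flagged$ind1, flagged$ind2))
      flagged <- flagged[!key %in% accepted, , drop = FALSE]
    }
    if (!nrow(flagged)) break
    pair <- flagged[1, ]
    both_f <- all(c(pair$ind1, pair$ind2) %in% founders)
    if (both_f) {
      accepted <- c(accepted, paste(pmin(pair$ind1, pair$ind2),
                                    pmax(pair$ind1, pair$ind2)))
      log <- rbind(log, data.frame(subgroup = NA_character_, iteration = it,
                                   removed = NA_character_,
                                   replacement = NA_character_,
                                   flagged = sprintf("founder pair kept: %s/%s",
                                                     pair$ind1, pair$ind2)))
      warning(sprintf("first-degree founder pair kept: %s / %s",
                      pair$ind1, pair$ind2))
      next
    }
    members <- c(pair$ind1, pair$ind2)
    removable <- members[!members %in% founders]
    rest <- setdiff(pool, members)
    drop_id <- if (length(removable) == 1) removable else {
      meank <- vapply(removable, function(i) mean(Kais[i, rest]), numeric(1))
      removable[order(-meank, removable)][1]
    }
    g <- subgroups[vapply(subgroups, function(g) drop_id %in% selection[[g]],
                          logical(1))][1]
    candidates[[g]] <- setdiff(candidates[[g]], drop_id)
    keep <- setdiff(selection[[g]], drop_id)
    if (length(candidates[[g]]) < subgroupSize)
      stop(sprintf("subgroup %s exhausted: %d candidates left for target %d",
                   g, length(candidates[[g]]), subgroupSize))
    refilled <- maximinSubsample(
      D[candidates[[g]], candidates[[g]], drop = FALSE],
      subgroupSize, keep)
    newcomer <- setdiff(refilled, keep)
    selection[[g]] <- refilled
    log <- rbind(log, data.frame(subgroup = g, iteration = it,
                                 removed = drop_id,
                                 replacement = paste(newcomer, collapse = ","),
                                 flagged = NA_character_))
  }
  new("PanelSelection", selection = selection, founders = founders,
      log = log, targetSize = as.integer(subgroupSize))
}

#' Representativeness of a panel against its source collection
#'
#' Allele retention (fraction of collection alleles with frequency above
#' \code{rareMaf} that are present in the panel), squared Pearson
#' correlation of allele frequencies, and per phenotype: Wilcoxon rank-sum
#' mean-equality test (normal approximation with tie correction),
#' Brown-Forsythe (median-centred Levene) variance-equality test, and the
#' fraction of collection variance captured by the panel.
#'
#' @param panel a [PanelSelection-class] or character vector of panel ids.
#' @param collection the source [GenotypePanel-class].
#' @param phenotypes optional data.frame with \code{ind_id} plus one column
#'   per quantitative trait, covering the collection.
#' @param rareMaf rare-allele threshold (default 0.05).
#' @return list with \code{allele_retention}, \code{freq_r2}, \code{freqs}
#'   (per-allele panel vs collection table) and \code{traits} (per-trait
#'   test results), of class "RepresentativenessReport".
#' @export
assessRepresentativeness <- function(panel, collection, phenotypes = NULL,
                                     rareMaf = 0.05) {
  pids <- if (is(panel, "PanelSelection")) panelIds(panel) else panel
  if (!all(pids %in% indIds(collection)))
    stop("panel ids must be a subset of the collection")
  pgm <- collection[pids, ]
  fc <- alleleFrequencies(collection)
  fp <- alleleFrequencies(pgm)
  key <- function(d) paste(d$locus_id, d$allele)
  fp_at <- fp$freq[match(key(fc), key(fp))]
  fp_at[is.na(fp_at)] <- 0
  present_c <- !is.na(fc$freq) & fc$freq > 0
  common <- present_c & fc$freq > rareMaf
  retention <- if (any(common)) mean(fp_at[common] > 0) else NA_real_
  use <- present_c
  freq_r2 <- stats::cor(fc$freq[use], fp_at[use])^2
  traits <- NULL
  if (!is.null(phenotypes)) {
    stopifnot("ind_id" %in% names(phenotypes))
    inpanel <- phenotypes$ind_id %in% pids
    tr <- setdiff(names(phenotypes), "ind_id")
    rows <- list()
    for (t in tr) {
      yp <- phenotypes[[t]][inpanel]
      yc <- phenotypes[[t]]
      yp <- yp[!is.na(yp)]; yc <- yc[!is.na(yc)]
      if (length(yp) < 3) {
        warning(sprintf("trait '%s': fewer than 3 panel values; skipped", t))
        next
      }
      wt <- suppressWarnings(stats::wilcox.test(yp, yc, exact = FALSE,
                                                correct = TRUE))
      lev <- car::leveneTest(
        c(yp, yc), factor(rep(c("panel", "collection"),
                              c(length(yp), length(yc)))),
        center = stats::median)
      rows[[t]] <- data.frame(
        trait = t, n_panel = length(yp), n_collection = length(yc),
        ranksum_W = unname(wt$statistic), ranksum_p = wt$p.value,
        levene_F = lev[1, "F value"], levene_p = lev[1, "Pr(>F)"],
        var_captured = stats::var(yp) / stats::var(yc))
    }
    traits <- do.call(rbind, rows)
    rownames(traits) <- NULL
  }
  out <- list(allele_retention = retention, freq_r2 = freq_r2,
              freqs = data.frame(locus_id = fc$locus_id, allele = fc$allele,
                                 freq_collection = fc$freq,
                                 freq_panel = fp_at)[present_c, ],
              traits = traits, rare_maf = rareMaf)
  class(out) <- "RepresentativenessReport"
  out
}
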