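#' @include diversity.R
NULL

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

# Balding-Nichols subgroup frequency around ancestral p at differentiation F
.bnFreq <- function(p, F) {
  if (F <= 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Configuration for the synthetic structured-panel generator
#'
#' Defaults emulate a curated germplasm collection sampled into three
#' cultivated subgroups (90, 92, 90 individuals) plus a smaller wild group
#' (62), genotyped at four clustered ~2 Mb genomic regions holding 372 SNPs
#' in total, 129 genome-distributed SNPs and 20 multiallelic SSR loci, with
#' Balding-Nichols subgroup differentiation in the 0.01-0.09 range and LD
#' within regions generated by a haplotype-pool copying model.
#'
#' @param seed integer seed; every random draw of the generator flows from
#'   it.
#' @param groupSizes named integer vector of panel sizes.
#' @param fstTargets named numeric vector, per-group Balding-Nichols F; the
#'   realised pairwise differentiation between two groups is approximately
#'   the mean of their F values.
#' @param ancestralMafRange interval the ancestral SNP allele frequencies
#'   are drawn from (uniform, with random choice of which allele is minor).
#' @param regions data.frame with \code{chrom}, \code{start_bp},
#'   \code{length_bp}, \code{n_snps}: the clustered regions carrying LD.
#' @param nDistributedSnps number of genome-distributed SNPs (no LD; drawn
#'   independently per individual from the subgroup frequencies).
#' @param nSsr number of SSR loci (no LD).
#' @param ssrAlleleRange allele-count range for SSR loci.
#' @param haplotypePoolSize named integer vector: per-group founder
#'   haplotype pool size for the regions. Small pools give high short-range
#'   LD (background r2 near 1/(H-1)); the wild default is half the
#'   cultivated one, mirroring its reduced diversity and longer LD.
#' @param switchRate per-bp probability that the copying process switches to
#'   a (uniformly drawn) pool haplotype; controls the LD decay rate.
#' @param relatedPairs list with integers \code{PO} and \code{FS}: number of
#'   parent-offspring and full-sib pairs to inject per cultivated subgroup
#'   via [injectRelatives()].
#' @param qBlur in [0, 1): 0 gives an indicator membership matrix; positive
#'   values blur it with a Dirichlet draw concentrated on the true group.
#' @return list of settings (class "SimulationConfig").
#' @export
simulationConfig <- function(seed = 1L,
                             groupSizes = c(WE = 90L, WW = 92L, TE = 90L, wild = 62L),
                             fstTargets = c(WE = 0.03, WW = 0.05, TE = 0.03, wild = 0.09),
                             ancestralMafRange = c(0.05, 0.5),
                             regions = data.frame(
                               chrom = c("chr4", "chr9", "chr15", "chr17"),
                               start_bp = 1000000L,
                               length_bp = 2000000L,
                               n_snps = c(86L, 109L, 90L, 87L)),
                             nDistributedSnps = 129L,
                             nSsr = 20L,
                             ssrAlleleRange = c(8L, 15L),
                             haplotypePoolSize = c(WE = 6L, WW = 6L, TE = 6L, wild = 3L),
                             switchRate = 5e-6,
                             relatedPairs = list(PO = 0L, FS = 0L),
                             qBlur = 0) {
  stopifnot(all(groupSizes >= 0), all(fstTargets >= 0), all(fstTargets < 0.5),
            switchRate > 0, nDistributedSnps >= 0, nSsr >= 0,
            all(names(groupSizes) %in% names(fstTargets)),
            all(names(groupSizes) %in% names(haplotypePoolSize)))
  if (any(regions$n_snps > regions$length_bp))
    stop("n_snps exceeds region length in bp")
  cfg <- list(seed = as.integer(seed), groupSizes = groupSizes,
              fstTargets = fstTargets, ancestralMafRange = ancestralMafRange,
              regions = regions, nDistributedSnps = as.integer(nDistributedSnps),
              nSsr = as.integer(nSsr), ssrAlleleRange = ssrAlleleRange,
              haplotypePoolSize = haplotypePoolSize, switchRate = switchRate,
              relatedPairs = relatedPairs, qBlur = qBlur)
  class(cfg) <- "SimulationConfig"
  cfg
}

# copying process along one region for n gametes: templates switch between
# pool haplotypes with per-bp rate; returns n x L allele matrix
.copyGametes <- function(pool, pos, n, rate) {
  H <- nrow(pool); L <- length(pos)
  out <- matrix(0L, n, L)
  tmpl <- sample.int(H, n, replace = TRUE)
  out[, 1] <- pool[tmpl, 1]
  if (L > 1) for (j in 2:L) {
    keep <- stats::runif(n) < exp(-rate * (pos[j] - pos[j - 1]))
    nsw <- sum(!keep)
    if (nsw) tmpl[!keep] <- sample.int(H, nsw, replace = TRUE)
    out[, j] <- pool[tmpl, j]
  }
  out
}

#' Simulate a structured diversity panel
#'
#' Ancestral SNP frequencies are drawn uniformly from
#' \code{ancestralMafRange} (random minor-allele side); subgroup frequencies
#' follow the Balding-Nichols Beta model at the per-group F. Within each
#' clustered region, each subgroup owns a small pool of founder haplotypes
#' (alleles drawn site-wise from the subgroup frequencies) and every gamete
#' is generated by copying along the region from a pool haplotype, switching
#' templates with per-bp probability \code{switchRate} -- producing r2 that
#' decays with physical distance towards the sampling background.
#' Distributed SNPs and SSR alleles are drawn independently per individual
#' (no LD). The membership matrix Q is the generating group indicator
#' (optionally Dirichlet-blurred). Deterministic under the config seed.
#'
#' @param cfg a [simulationConfig()].
#' @return list (class "PanelSimulation") with \code{panel}
#'   ([GenotypePanel-class]), \code{Q} ([StructureMatrix-class]) and
#'   \code{truth} (generator-side ground truth: subgroup frequencies,
#'   haplotype pools, per-individual gametes, injected-relative registry).
#' @export
simulatePanel <- function(cfg = simulationConfig()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  groups <- names(cfg$groupSizes)
  n_by_g <- cfg$groupSizes
  N <- sum(n_by_g)
  grp <- rep(groups, n_by_g)
  ids <- sprintf("%s_%03d", grp, unlist(lapply(n_by_g, seq_len)))

  # --- locus map ---------------------------------------------------------
  loc_list <- list()
  for (r in seq_len(nrow(cfg$regions))) {
    rg <- cfg$regions[r, ]
    pos <- sort(sample.int(rg$length_bp, rg$n_snps)) + rg$start_bp - 1L
    loc_list[[length(loc_list) + 1L]] <- data.frame(
      locus_id = sprintf("R%d_snp%03d", r, seq_len(rg$n_snps)),
      chrom = rg$chrom, pos_bp = pos, locus_type = "snp",
      region = sprintf("region%d", r))
  }
  if (cfg$nDistributedSnps > 0) {
    chr <- sprintf("chr%d", rep_len(1:19, cfg$nDistributedSnps))
    loc_list[[length(loc_list) + 1L]] <- data.frame(
      locus_id = sprintf("D_snp%03d", seq_len(cfg$nDistributedSnps)),
      chrom = chr,
      pos_bp = sample.int(20000000L, cfg$nDistributedSnps, replace = TRUE),
      locus_type = "snp", region = "distributed")
  }
  if (cfg$nSsr > 0) {
    loc_list[[length(loc_list) + 1L]] <- data.frame(
      locus_id = sprintf("ssr%02d", seq_len(cfg$nSsr)),
      chrom = sprintf("chr%d", rep_len(1:19, cfg$nSsr)),
      pos_bp = sample.int(20000000L, cfg$nSsr, replace = TRUE),
      locus_type = "ssr", region = NA_character_)
  }
  loci <- do.call(rbind, loc_list)
  snp_loc <- loci[loci$locus_type == "snp", ]
  Lsnp <- nrow(snp_loc)

  # --- SNP frequencies (ancestral + Balding-Nichols subgroup) ------------
  p_anc <- stats::runif(Lsnp, cfg$ancestralMafRange[1], cfg$ancestralMafRange[2])
  flip <- stats::runif(Lsnp) < 0.5
  p_anc[flip] <- 1 - p_anc[flip]
  p_grp <- sapply(groups, function(g) .bnFreq(p_anc, cfg$fstTargets[[g]]))
  rownames(p_grp) <- snp_loc$locus_id

  # --- gametes -----------------------------------------------------------
  gamA <- gamB <- matrix(0L, N, Lsnp, dimnames = list(ids, snp_loc$locus_id))
  pools <- list()
  region_idx <- split(seq_len(Lsnp), snp_loc$region)
  for (rname in names(region_idx)) {
    jj <- region_idx[[rname]]
    if (rname == "distributed") {
      for (g in groups) {
        rows <- which(grp == g)
        pg <- p_grp[jj, g]
        gamA[rows, jj] <- stats::rbinom(length(rows) * length(jj), 1,
                                        rep(pg, each = length(rows)))
        gamB[rows, jj] <- stats::rbinom(length(rows) * length(jj), 1,
                                        rep(pg, each = length(rows)))
      }
      next
    }
    pools[[rname]] <- list()
    pos <- snp_loc$pos_bp[jj]
    for (g in groups) {
      H <- cfg$haplotypePoolSize[[g]]
      pool <- matrix(stats::rbinom(H * length(jj), 1,
                                   rep(p_grp[jj, g], each = H)), nrow = H)
      pools[[rname]][[g]] <- pool
      rows <- which(grp == g)
      gamA[rows, jj] <- .copyGametes(pool, pos, length(rows), cfg$switchRate)
      gamB[rows, jj] <- .copyGametes(pool, pos, length(rows), cfg$switchRate)
    }
  }
  snp <- (gamA + gamB) / 2

  # --- SSR loci ----------------------------------------------------------
  ssrA <- ssrB <- matrix(integer(0), N, 0)
  ssr_freqs <- list()
  if (cfg$nSsr > 0) {
    ssr_ids <- loci$locus_id[loci$locus_type == "ssr"]
    ssrA <- ssrB <- matrix(NA_integer_, N, cfg$nSsr,
                           dimnames = list(ids, ssr_ids))
    for (l in seq_len(cfg$nSsr)) {
      A <- sample(seq(cfg$ssrAlleleRange[1], cfg$ssrAlleleRange[2]), 1)
      f_anc <- as.vector(.rdirichlet(1, rep(1, A)))
      ssr_freqs[[ssr_ids[l]]] <- list(ancestral = f_anc)
      for (g in groups) {
        F <- cfg$fstTargets[[g]]
        f_g <- if (F <= 0) f_anc
               else as.vector(.rdirichlet(1, f_anc * (1 - F) / F))
        ssr_freqs[[ssr_ids[l]]][[g]] <- f_g
        rows <- which(grp == g)
        ssrA[rows, l] <- sample.int(A, length(rows), replace = TRUE, prob = f_g)
        ssrB[rows, l] <- sample.int(A, length(rows), replace = TRUE, prob = f_g)
      }
    }
  }

  # --- membership matrix -------------------------------------------------
  K <- length(groups)
  if (cfg$qBlur > 0) {
    alpha_base <- 50 * ((1 - cfg$qBlur) * diag(K) + cfg$qBlur / K)
    Q <- matrix(0, N, K)
    for (i in seq_len(N))
      Q[i, ] <- .rdirichlet(1, alpha_base[match(grp[i], groups), ] + 1e-3)
  } else {
    Q <- diag(K)[match(grp, groups), , drop = FALSE]
  }
  dimnames(Q) <- list(ids, groups)

  panel <- GenotypePanel(
    snp = snp,
    ssr = if (cfg$nSsr > 0) list(a1 = ssrA, a2 = ssrB) else NULL,
    loci = loci,
    individuals = data.frame(ind_id = ids, subgroup = grp, founder = FALSE))

  truth <- list(groupLabels = grp, ancestralFreqs = p_anc, groupFreqs = p_grp,
                pools = pools, gametes = list(A = gamA, B = gamB),
                ssrFreqs = ssr_freqs,
                registry = data.frame(ind1 = character(), ind2 = character(),
                                      relationship = character(),
                                      group = character()))
  out <- list(panel = panel, Q = structureMatrix(Q), truth = truth, cfg = cfg)
  class(out) <- "PanelSimulation"
  out
}

# draw one fresh individual of group g (gametes + ssr) from the generator
# truth; returns list(gamA, gamB, ssrA, ssrB)
.freshIndividual <- function(sim, g) {
  cfg <- sim$cfg; truth <- sim$truth
  loci <- sim$panel@loci
  snp_loc <- loci[loci$locus_type == "snp", ]
  L <- nrow(snp_loc)
  gA <- gB <- integer(L)
  region_idx <- split(seq_len(L), snp_loc$region)
  for (rname in names(region_idx)) {
    jj <- region_idx[[rname]]
    if (rname == "distributed") {
      pg <- truth$groupFreqs[jj, g]
      gA[jj] <- stats::rbinom(length(jj), 1, pg)
      gB[jj] <- stats::rbinom(length(jj), 1, pg)
    } else {
      pos <- snp_loc$pos_bp[jj]
      pool <- truth$pools[[rname]][[g]]
      gA[jj] <- .copyGametes(pool, pos, 1, cfg$switchRate)[1, ]
      gB[jj] <- .copyGametes(pool, pos, 1, cfg$switchRate)[1, ]
    }
  }
  nssr <- ncol(sim$panel@ssrA)
  sA <- sB <- integer(0)
  if (nssr) {
    sA <- sB <- integer(nssr)
    for (l in seq_len(nssr)) {
      f <- truth$ssrFreqs[[colnames(sim$panel@ssrA)[l]]][[g]]
      sA[l] <- sample.int(length(f), 1, prob = f)
      sB[l] <- sample.int(length(f), 1, prob = f)
    }
  }
  list(gamA = gA, gamB = gB, ssrA = sA, ssrB = sB)
}

# child of two parent individuals (each a list as from .freshIndividual):
# one recombination-free gamete per region from each parent; independent
# allele choice per distributed SNP and SSR locus
.childOf <- function(sim, par1, par2) {
  loci <- sim$panel@loci
  snp_loc <- loci[loci$locus_type == "snp", ]
  L <- nrow(snp_loc)
  pick <- function(par) {
    gam <- integer(L)
    region_idx <- split(seq_len(L), snp_loc$region)
    for (rname in names(region_idx)) {
      jj <- region_idx[[rname]]
      if (rname == "distributed") {
        takeA <- stats::runif(length(jj)) < 0.5
        gam[jj] <- ifelse(takeA, par$gamA[jj], par$gamB[jj])
      } else {
        gam[jj] <- if (stats::runif(1) < 0.5) par$gamA[jj] else par$gamB[jj]
      }
    }
    gam
  }
  nssr <- length(par1$ssrA)
  sspick <- function(par) {
    takeA <- stats::runif(nssr) < 0.5
    as.integer(ifelse(takeA, par$ssrA, par$ssrB))
  }
  list(gamA = pick(par1), gamB = pick(par2),
       ssrA = sspick(par1), ssrB = sspick(par2))
}

.setIndividual <- function(sim, row, geno) {
  sim$truth$gametes$A[row, ] <- geno$gamA
  sim$truth$gametes$B[row, ] <- geno$gamB
  sim$panel@snp[row, ] <- (geno$gamA + geno$gamB) / 2
  if (length(geno$ssrA)) {
    a <- pmin(geno$ssrA, geno$ssrB); b <- pmax(geno$ssrA, geno$ssrB)
    sim$panel@ssrA[row, ] <- a
    sim$panel@ssrB[row, ] <- b
  }
  sim
}

.indAsParent <- function(sim, row) {
  list(gamA = sim$truth$gametes$A[row, ], gamB = sim$truth$gametes$B[row, ],
       ssrA = sim$panel@ssrA[row, ], ssrB = sim$panel@ssrB[row, ])
}

#' Inject first-degree relative pairs into a simulated panel
#'
#' Parent-offspring pairs: an existing individual is designated parent and
#' another slot is overwritten with a child carrying one recombination-free
#' parental gamete per region (random parental allele at unlinked loci) plus
#' a fresh gamete from the group's pool. Full-sib pairs: two slots are
#' overwritten with two children of the same two freshly drawn pool parents.
#' The truth registry records every injected pair.
#'
#' @param sim a "PanelSimulation" from [simulatePanel()].
#' @param poPerGroup,fsPerGroup number of PO / FS pairs per cultivated
#'   subgroup (defaults from \code{sim$cfg$relatedPairs}).
#' @param groups subgroups to inject into (default: all but "wild").
#' @return the modified "PanelSimulation" (registry updated).
#' @export
injectRelatives <- function(sim,
                            poPerGroup = sim$cfg$relatedPairs$PO,
                            fsPerGroup = sim$cfg$relatedPairs$FS,
                            groups = setdiff(names(sim$cfg$groupSizes), "wild")) {
  stopifnot(inherits(sim, "PanelSimulation"))
  if (poPerGroup == 0 && fsPerGroup == 0) return(sim)
  grp <- sim$truth$groupLabels
  ids <- indIds(sim$panel)
  for (g in groups) {
    rows <- which(grp == g)
    used <- ids %in% c(sim$truth$registry$ind1, sim$truth$registry$ind2)
    avail <- rows[!used[rows]]
    need <- 2 * (poPerGroup + fsPerGroup)
    if (length(avail) < need)
      stop(sprintf("group %s: %d individuals available, %d needed for relative pairs",
                   g, length(avail), need))
    avail <- sample(avail) # deterministic under the ambient RNG stream
    k <- 1
    for (i in seq_len(poPerGroup)) {
      parent <- avail[k]; child <- avail[k + 1]; k <- k + 2
      par1 <- .indAsParent(sim, parent)
      par2 <- .freshIndividual(sim, g)
      sim <- .setIndividual(sim, child, .childOf(sim, par1, par2))
      sim$truth$registry <- rbind(sim$truth$registry,
        data.frame(ind1 = ids[parent], ind2 = ids[child],
                   relationship = "PO", group = g))
    }
    for (i in seq_len(fsPerGroup)) {
      c1 <- avail[k]; c2 <- avail[k + 1]; k <- k + 2
      par1 <- .freshIndividual(sim, g)
      par2 <- .freshIndividual(sim, g)
      sim <- .setIndividual(sim, c1, .childOf(sim, par1, par2))
      sim <- .setIndividual(sim, c2, .childOf(sim, par1, par2))
      sim$truth$registry <- rbind(sim$truth$registry,
        data.frame(ind1 = ids[c1], ind2 = ids[c2],
                   relationship = "FS", group = g))
    }
  }
  sim
}

#' Simulate a phenotype under the association mixed model
#'
#' Y = 1 mu + x beta + U + E on a unit total-variance scale: residual
#' variance sigma2_e = 1 - h2, polygenic U ~ N(0, K sigma2_gl) with
#' sigma2_gl = (1 - qEffect) h2, and beta chosen so that
#' beta^2 Var_emp(x) = qEffect * h2 (empirical genotype variance, no HWE
#' assumption).
#'
#' @param gm a [GenotypePanel-class].
#' @param K a [KinshipMatrix-class] (negative entries truncated at 0 and
#'   ridged before factorisation).
#' @param h2 heritability in [0, 1].
#' @param qEffect fraction of additive genetic variance at the causal locus.
#' @param causal SNP locus_id of the causal locus (must be polymorphic).
#' @param seed integer seed.
#' @param mu intercept (default 0).
#' @return named numeric phenotype vector.
#' @export
simulatePhenotype <- function(gm, K, h2, qEffect, causal, seed, mu = 0) {
  stopifnot(h2 >= 0, h2 <= 1, qEffect >= 0, qEffect <= 1)
  x <- gm@snp[, causal]
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  vx <- stats::var(x)
  if (vx == 0) stop(sprintf("causal locus '%s' is monomorphic", causal))
  set.seed(seed)
  N <- length(x)
  beta <- sqrt(qEffect * h2 / vx)
  s2_gl <- (1 - qEffect) * h2
  s2_e <- 1 - h2
  U <- if (s2_gl > 0) {
    R <- chol(.preparePD(as.matrix(K)))
    drop(t(R) %*% stats::rnorm(N)) * sqrt(s2_gl)
  } else rep(0, N)
  E <- stats::rnorm(N, sd = sqrt(s2_e))
  setNames(mu + beta * x + U + E, indIds(gm))
}
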