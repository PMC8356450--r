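#' Selected-population configuration
#'
#' Parameters of the breeding scheme layered on top of the founder
#' population: discrete generations of truncation selection on pedigree EBVs
#' with partial sire/dam replacement, phenotypes simulated as TBV plus normal
#' residual, and random genotyping of half the phenotyped training
#' individuals.
#'
#' @param nGenerations number of progeny generations; the last one is the
#'   genotyped, unphenotyped validation generation.
#' @param progenyPerGeneration progeny born per generation.
#' @param nSires,nDams numbers of active sires and dams (their sum must equal
#'   the founder count).
#' @param sireReplacement,damReplacement proportion of parents replaced each
#'   generation by top-ranked young candidates.
#' @param varG,varE additive-genetic and residual variance of the trait
#'   (heritability \code{varG/(varG+varE)}).
#' @param genotypedFractionTraining fraction of each phenotyped generation
#'   genotyped at random.
#' @param h2 optional heritability; must equal \code{varG / (varG + varE)}
#'   when supplied.
#' @return a list of class \code{selectionConfig}.
#' @export
selectionConfig <- function(nGenerations = 7L, progenyPerGeneration = 3500L,
                            nSires = 500L, nDams = 3500L,
                            sireReplacement = 0.5, damReplacement = 0.2,
                            varG = 0.4, varE = 0.6,
                            genotypedFractionTraining = 0.5, h2 = NULL) {
  if (sireReplacement < 0 || sireReplacement > 1 || damReplacement < 0 ||
      damReplacement > 1)
    stop("replacement rates must lie in [0, 1]")
  if (varG <= 0 || varE < 0) stop("variances must be positive")
  if (!is.null(h2) && abs(h2 - varG / (varG + varE)) > 1e-8)
    stop("h2 inconsistent with varG/(varG + varE)")
  structure(list(nGenerations = as.integer(nGenerations),
                 progenyPerGeneration = as.integer(progenyPerGeneration),
                 nSires = as.integer(nSires), nDams = as.integer(nDams),
                 sireReplacement = sireReplacement,
                 damReplacement = damReplacement, varG = varG, varE = varE,
                 h2 = varG / (varG + varE),
                 genotypedFractionTraining = genotypedFractionTraining),
            class = "selectionConfig")
}

#' Simulate the selected population
#'
#' Sexes the founders (\code{nSires} males, \code{nDams} females, at random),
#' then breeds \code{nGenerations} generations. From the second generation
#' on, parents are ranked on pedigree EBVs from an A-matrix BLUP fit of all
#' phenotypes recorded so far; the lowest-ranked fraction of each sex is
#' culled and replaced by the top-ranked candidates of the previous
#' generation. Selected dams are shuffled and allocated evenly to sires; each
#' progeny draws one gamete from its sire and one from its dam. Phenotypes
#' (TBV + N(0, varE)) are assigned at birth in all but the last generation;
#' the last generation is fully genotyped and unphenotyped.
#'
#' @param pop founder [Population-class] with QTL effects assigned.
#' @param sel a [selectionConfig()].
#' @return a [Population-class] covering founders and all progeny.
#' @export
simulateSelectedPopulation <- function(pop, sel) {
  stopifnot(is(pop, "Population"), inherits(sel, "selectionConfig"))
  if (!length(pop@qtlEffects)) stop("assign QTL effects first")
  n0 <- nrow(pop@pedigree)
  if (n0 != sel$nSires + sel$nDams)
    stop("founder count (", n0, ") must equal nSires + nDams (",
         sel$nSires + sel$nDams, ")")
  blocks <- chromBlocks(pop@map)
  nloci <- nrow(pop@map@loci)
  qtl <- qtlLoci(pop)
  eff <- pop@qtlEffects[as.character(qtl)]
  nTot <- n0 + sel$nGenerations * sel$progenyPerGeneration

  sex <- rep("F", n0)
  sex[sample.int(n0, sel$nSires)] <- "M"
  ped <- data.frame(id = seq_len(nTot), sire = 0L, dam = 0L,
                    generation = 0L, sex = NA_character_)
  ped$sex[seq_len(n0)] <- sex
  haps <- matrix(as.raw(0), nloci, 2L * nTot)
  haps[, seq_len(2L * n0)] <- pop@haps
  tbv <- rep(NA_real_, nTot); tbv[seq_len(n0)] <- pop@tbv
  phen <- rep(NA_real_, nTot)
  genod <- rep(FALSE, nTot)

  sires <- which(ped$sex[seq_len(n0)] == "M")
  dams <- which(ped$sex[seq_len(n0)] == "F")
  nCur <- n0
  for (g in seq_len(sel$nGenerations)) {
    if (g >= 2L) {
      fit <- solveABlup(phen[seq_len(nCur)], ped[seq_len(nCur), ],
                        varG = sel$varG, varE = sel$varE)
      ebv <- fit$ebv
      prev <- which(ped$generation[seq_len(nCur)] == g - 1L)
      replaceParents <- function(cur, rate, nKeep, candSex) {
        nRep <- round(rate * nKeep)
        if (nRep == 0L) return(cur)
        cand <- setdiff(prev[ped$sex[prev] == candSex], cur)
        if (length(cand) < nRep)
          stop("insufficient ", candSex, " candidates in generation ",
               g - 1L, " (need ", nRep, ", have ", length(cand), ")")
        keep <- cur[order(ebv[cur], decreasing = TRUE)][seq_len(nKeep - nRep)]
        young <- cand[order(ebv[cand], decreasing = TRUE)][seq_len(nRep)]
        c(keep, young)
      }
      sires <- replaceParents(sires, sel$sireReplacement, sel$nSires, "M")
      dams <- replaceParents(dams, sel$damReplacement, sel$nDams, "F")
    }
    nOff <- sel$progenyPerGeneration
    damSeq <- rep_len(sample(dams), nOff)
    sireForDam <- setNames(
      rep(sample(sires), each = ceiling(length(dams) / length(sires)))[
        seq_along(dams)], dams)
    sireSeq <- sireForDam[as.character(damSeq)]
    off <- cpp_drop_generation(haps[, seq_len(2L * nCur), drop = FALSE],
                               as.integer(sireSeq), as.integer(damSeq),
                               blocks$start, blocks$end, blocks$pos,
                               blocks$len)
    idx <- nCur + seq_len(nOff)
    haps[, 2L * nCur + seq_len(2L * nOff)] <- off
    ped$sire[idx] <- as.integer(sireSeq)
    ped$dam[idx] <- damSeq
    ped$generation[idx] <- g
    ped$sex[idx] <- sample(c("M", "F"), nOff, replace = TRUE)
    tbvOff <- drop(cpp_dosage(off, as.integer(qtl),
                              as.integer(seq_len(nOff))) %*% eff)
    tbv[idx] <- tbvOff
    if (g < sel$nGenerations) {
      phen[idx] <- tbvOff + rnorm(nOff, 0, sqrt(sel$varE))
      genod[idx[sample.int(nOff,
        round(sel$genotypedFractionTraining * nOff))]] <- TRUE
    } else {
      genod[idx] <- TRUE
    }
    nCur <- nCur + nOff
  }
  out <- new("Population", haps = haps, map = pop@map, pedigree = ped,
             tbv = tbv, phenotype = phen, genotyped = genod,
             qtlEffects = pop@qtlEffects, ldSummary = pop@ldSummary)
  g1 <- ped$generation == 1L
  out@ldSummary$founderTbvVar <- var(pop@tbv)
  out@ldSummary$gen1PhenVar <- var(phen[g1])
  out@ldSummary$gen1RealizedH2 <- var(tbv[g1]) / var(phen[g1])
  out
}
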