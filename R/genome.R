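#' Genome configuration
#'
#' Describes the linkage map to simulate: evenly spaced SNP markers on equal
#' length chromosomes plus causal QTL confined to designated chromosomes.
#' QTL positions are drawn uniformly and kept distinct from SNP positions; a
#' surplus of candidate QTL positions (\code{qtlCandidateFactor * nQtl}) is
#' carried through the historical simulation so that the requested number of
#' QTL can later be picked from positions still segregating.
#'
#' @param nChromosomes number of chromosomes.
#' @param chromLengthCM chromosome length in centiMorgans.
#' @param nSnpsTotal total SNP count, divisible by \code{nChromosomes}.
#' @param nQtl number of (segregating) QTL for the trait.
#' @param qtlChromosomes chromosome indices carrying the QTL.
#' @param qtlEffectShape shape of the Gamma distribution of absolute QTL
#'   effects.
#' @param qtlCandidateFactor how many candidate QTL positions to lay out per
#'   requested QTL.
#' @param snpCandidateFactor density multiplier of the evenly spaced SNP
#'   candidate grid. With the default 1 the panel is the simulated grid
#'   itself (loci drifting to fixation stay in the map as monomorphic
#'   markers). Above 1, [simulateHistorical()] draws the requested number of
#'   markers per chromosome from the candidates still segregating after the
#'   historical generations, as QMSim-style simulators do, so that the panel
#'   consists of informative SNPs even under strong drift.
#' @return a list of class \code{genomeConfig}.
#' @export
genomeConfig <- function(nChromosomes = 30L, chromLengthCM = 100,
                         nSnpsTotal = 777000L, nQtl = 200L,
                         qtlChromosomes = c(1L, 2L), qtlEffectShape = 0.4,
                         qtlCandidateFactor = 20L, snpCandidateFactor = 1L) {
  if (nSnpsTotal %% nChromosomes != 0L)
    stop("nSnpsTotal must be divisible by nChromosomes")
  if (nQtl > 0L && !all(qtlChromosomes %in% seq_len(nChromosomes)))
    stop("qtlChromosomes out of range")
  structure(list(nChromosomes = as.integer(nChromosomes),
                 chromLengthCM = chromLengthCM,
                 nSnpsTotal = as.integer(nSnpsTotal), nQtl = as.integer(nQtl),
                 qtlChromosomes = as.integer(qtlChromosomes),
                 qtlEffectShape = qtlEffectShape,
                 qtlCandidateFactor = as.integer(qtlCandidateFactor),
                 snpCandidateFactor = as.integer(snpCandidateFactor)),
            class = "genomeConfig")
}

#' Build the genome map
#'
#' Lays out \code{nSnpsTotal/nChromosomes} evenly spaced SNPs per chromosome
#' (midpoints of equal bins, so no SNP sits on a chromosome end) and draws
#' candidate QTL positions uniformly on the designated chromosomes. Uses the
#' current RNG state for the QTL positions.
#'
#' @param config a [genomeConfig()].
#' @return a [GenomeMap-class].
#' @export
buildGenomeMap <- function(config) {
  stopifnot(inherits(config, "genomeConfig"))
  perChrom <- (config$nSnpsTotal %/% config$nChromosomes) *
    config$snpCandidateFactor
  snp <- data.frame(
    chrom = rep(seq_len(config$nChromosomes), each = perChrom),
    posCM = rep((seq_len(perChrom) - 0.5) * config$chromLengthCM / perChrom,
                config$nChromosomes),
    type = if (config$snpCandidateFactor > 1L) "snp_cand" else "snp")
  nCand <- config$nQtl * config$qtlCandidateFactor
  if (nCand > 0L) {
    qchrom <- sample(config$qtlChromosomes, nCand, replace = TRUE)
    qpos <- runif(nCand, 0, config$chromLengthCM)
    while (any(dup <- qpos %in% snp$posCM))           # distinct from SNPs
      qpos[dup] <- runif(sum(dup), 0, config$chromLengthCM)
    cand <- data.frame(chrom = qchrom, posCM = qpos, type = "candidate")
  } else {
    cand <- snp[0, ]
  }
  loci <- rbind(snp, cand)
  loci <- loci[order(loci$chrom, loci$posCM), ]
  loci$locus <- seq_len(nrow(loci))
  loci$class <- ifelse(loci$type %in% c("snp", "snp_cand"),
                       ifelse(loci$chrom %in% config$qtlChromosomes,
                              "HQ", "LQ"), NA_character_)
  rownames(loci) <- NULL
  new("GenomeMap", loci = loci[, c("locus", "chrom", "posCM", "type",
                                   "class")], config = unclass(config))
}

#' Truth linkage labels of the marker panel
#'
#' Labels every SNP by whether it lies on a QTL-bearing chromosome
#' (\code{"HQ"}, truth-linked) or on a QTL-free chromosome (\code{"LQ"},
#' truth-unlinked).
#'
#' @param map a [GenomeMap-class] (or a [Population-class]).
#' @return named character vector over SNP locus ids.
#' @export
truthLabels <- function(map) {
  lc <- lociTable(map)
  snp <- lc[lc$type == "snp", ]
  setNames(snp$class, snp$locus)
}
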