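#' Assign QTL effects and true breeding values
#'
#' Picks the requested number of QTL at random from the candidate positions
#' still segregating in the founder population, draws absolute
#' allele-substitution effects from a Gamma distribution with the configured
#' shape, attaches a Bernoulli(0.5) random sign to each, and rescales all
#' effects by one global constant so that the variance of the true breeding
#' value (the cross-product of QTL dosages and effects) among the founders
#' equals \code{varG}.
#'
#' @param pop founder [Population-class] from [simulateHistorical()].
#' @param varG target additive-genetic variance among founders.
#' @return the population with \code{qtlEffects}, founder \code{tbv}, an
#'   updated map (chosen candidates promoted to type \code{"qtl"}) and a
#'   refreshed LD summary.
#' @export
assignQtlEffects <- function(pop, varG = 0.4) {
  cfg <- pop@map@config
  lc <- pop@map@loci
  cand <- lc$locus[lc$type == "candidate"]
  if (cfg$nQtl == 0L) return(pop)
  if (!length(cand)) stop("map has no candidate QTL positions")
  freq <- alleleFreqs(pop, cand)
  seg <- cand[freq > 0 & freq < 1]
  if (length(seg) < cfg$nQtl)
    stop("only ", length(seg), " candidate QTL positions segregate; ",
         cfg$nQtl, " required (increase qtlCandidateFactor)")
  chosen <- sort(sample(seg, cfg$nQtl))
  mag <- rgamma(cfg$nQtl, shape = cfg$qtlEffectShape, scale = 1)
  eff <- mag * sample(c(-1, 1), cfg$nQtl, replace = TRUE)
  tbv <- drop(dosageMatrix(pop, chosen) %*% eff)
  v <- var(tbv)
  if (!is.finite(v) || v <= 0)
    stop("founder TBV variance is zero; cannot scale QTL effects")
  eff <- eff * sqrt(varG / v)
  pop@qtlEffects <- setNames(eff, chosen)
  pop@tbv <- tbv * sqrt(varG / v)
  pop@map@loci$type[match(chosen, lc$locus)] <- "qtl"
  pop@ldSummary <- ldSummary(pop)
  pop
}

#' Active QTL locus ids of a population
#' @param pop a [Population-class].
#' @return integer locus ids.
#' @export
qtlLoci <- function(pop) {
  lc <- lociTable(pop)
  lc$locus[lc$type == "qtl"]
}

#' SNP locus ids of the marker panel
#' @param pop a [Population-class] or [GenomeMap-class].
#' @return integer locus ids.
#' @export
snpLoci <- function(pop) {
  lc <- lociTable(pop)
  lc$locus[lc$type == "snp"]
}
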