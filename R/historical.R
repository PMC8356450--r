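#' Historical population configuration
#'
#' Size schedule of the neutral random-mating generations that build linkage
#' disequilibrium by drift. The default schedule holds the population at
#' \code{baseSize} until the bottleneck generation, drops it to
#' \code{bottleneckSize} there, and grows linearly back to \code{finalSize}
#' by the last generation. The default \code{baseSize} of 2200 is calibrated
#' (via the drift-recombination recursion for E[r2], confirmed by
#' simulation) so that at full marker density (259 SNPs/cM) the realized
#' mean r2 between consecutive SNPs lands in the design's stated LD regime
#' of about 0.32; see the package vignette.
#'
#' @param nGenerations number of mating generations.
#' @param bottleneckGeneration generation index of the bottleneck.
#' @param baseSize diploid population size before the bottleneck.
#' @param bottleneckSize size at the bottleneck generation.
#' @param finalSize size of the last generation (the founders of the selected
#'   population).
#' @param sizes optional explicit integer vector of sizes for generations
#'   \code{0..nGenerations}, overriding the built-in schedule.
#' @return a list of class \code{historicalConfig} with the resolved
#'   \code{sizes} vector.
#' @export
historicalConfig <- function(nGenerations = 2070L,
                             bottleneckGeneration = 2000L, baseSize = 2200L,
                             bottleneckSize = 600L, finalSize = 4000L,
                             sizes = NULL) {
  nGenerations <- as.integer(nGenerations)
  if (is.null(sizes)) {
    sizes <- rep(as.integer(baseSize), nGenerations + 1L)
    if (nGenerations >= bottleneckGeneration && bottleneckGeneration >= 0L) {
      g <- bottleneckGeneration:nGenerations
      ramp <- nGenerations - bottleneckGeneration
      sizes[g + 1L] <- if (ramp == 0L) as.integer(bottleneckSize) else
        as.integer(round(bottleneckSize +
          (finalSize - bottleneckSize) * (g - bottleneckGeneration) / ramp))
    }
  }
  sizes <- as.integer(sizes)
  if (length(sizes) != nGenerations + 1L)
    stop("size schedule must cover generations 0..nGenerations (",
         nGenerations + 1L, " values, got ", length(sizes), ")")
  if (any(is.na(sizes) | sizes < 2L))
    stop("population sizes must be >= 2 for every generation")
  structure(list(nGenerations = nGenerations,
                 bottleneckGeneration = as.integer(bottleneckGeneration),
                 sizes = sizes), class = "historicalConfig")
}

#' Simulate the historical (LD-building) generations
#'
#' Generation 0 is initialized with all loci at allele frequency 0.5 and
#' independent alleles; linkage disequilibrium then accumulates purely by
#' drift through the size schedule (random union of gametes from two distinct
#' parents per offspring). Returns the final generation as a founder
#' population (pedigree generation 0, unknown parents), with the realized
#' mean r2 between consecutive segregating SNPs stored in \code{ldSummary}.
#'
#' @param map a [GenomeMap-class].
#' @param hist a [historicalConfig()].
#' @param verbose print progress every 500 generations.
#' @return a [Population-class] of the final generation.
#' @export
simulateHistorical <- function(map, hist, verbose = FALSE) {
  stopifnot(is(map, "GenomeMap"), inherits(hist, "historicalConfig"))
  blocks <- chromBlocks(map)
  nloci <- nrow(map@loci)
  # two buffers sized for the largest generation, alternated across
  # generations to avoid one allocation per generation
  maxN <- max(hist$sizes)
  bufA <- matrix(as.raw(0L), nloci, 2L * maxN)
  bufB <- matrix(as.raw(0L), nloci, 2L * maxN)
  cpp_fill_random(bufA, 2L * hist$sizes[1L])
  nPrev <- hist$sizes[1L]
  for (g in seq_len(hist$nGenerations)) {
    n <- hist$sizes[g + 1L]
    sire <- sample.int(nPrev, n, replace = TRUE)
    dam <- sample.int(nPrev, n, replace = TRUE)
    while (any(bad <- sire == dam))                  # no selfing
      dam[bad] <- sample.int(nPrev, sum(bad), replace = TRUE)
    cpp_drop_generation_into(bufA, nPrev, sire, dam, blocks$start,
                             blocks$end, blocks$pos, blocks$len, bufB)
    tmp <- bufA; bufA <- bufB; bufB <- tmp
    nPrev <- n
    if (verbose && g %% 500L == 0L)
      message("historical generation ", g, " (N = ", n, ")")
  }
  n <- hist$sizes[length(hist$sizes)]
  haps <- bufA[, seq_len(2L * n), drop = FALSE]
  rm(bufA, bufB)
  ped <- data.frame(id = seq_len(n), sire = 0L, dam = 0L, generation = 0L,
                    sex = NA_character_)
  pop <- new("Population", haps = haps, map = map, pedigree = ped,
             tbv = rep(NA_real_, n), phenotype = rep(NA_real_, n),
             genotyped = rep(FALSE, n), qtlEffects = numeric(0),
             ldSummary = list())
  if (any(map@loci$type == "snp_cand")) pop <- selectMarkerPanel(pop)
  freq <- alleleFreqs(pop, lociTable(pop)$locus)
  if (all(freq == 0 | freq == 1))
    stop("degenerate simulation: all loci fixed")
  pop@ldSummary <- ldSummary(pop)
  pop
}

# Draw the marker panel from the SNP candidates still segregating after the
# historical generations (per chromosome, uniformly at random, kept in map
# order), then drop the unused candidates from the map and haplotypes.
selectMarkerPanel <- function(pop) {
  cfg <- pop@map@config
  lc <- pop@map@loci
  perChrom <- cfg$nSnpsTotal %/% cfg$nChromosomes
  freq <- alleleFreqs(pop, lc$locus)
  seg <- freq > 0 & freq < 1
  chosen <- integer(0)
  for (ch in seq_len(cfg$nChromosomes)) {
    cand <- lc$locus[lc$type == "snp_cand" & lc$chrom == ch & seg]
    if (length(cand) < perChrom) {
      # fall back to monomorphic candidates for the shortfall; such markers
      # stay in the map but are excluded from G denominators and score
      # F_ST 0 downstream
      mono <- lc$locus[lc$type == "snp_cand" & lc$chrom == ch & !seg]
      warning("only ", length(cand), " of ", perChrom, " panel SNPs ",
              "segregate on chromosome ", ch,
              "; filling with monomorphic markers")
      cand <- c(cand, sample(mono, perChrom - length(cand)))
    } else {
      cand <- sample(cand, perChrom)
    }
    chosen <- c(chosen, sort(cand))
  }
  keep <- sort(c(chosen, lc$locus[!lc$type %in% "snp_cand"]))
  lc <- lc[match(keep, lc$locus), ]
  lc$type[lc$type == "snp_cand"] <- "snp"
  lc$locus <- seq_len(nrow(lc))
  rownames(lc) <- NULL
  pop@haps <- pop@haps[keep, , drop = FALSE]
  pop@map@loci <- lc
  pop
}

#' Realized linkage-disequilibrium summaries
#'
#' Mean gametic-phase r2 between consecutive segregating SNPs on the same
#' chromosome, between consecutive segregating QTL (candidates count as QTL
#' until effects are assigned), and between each segregating QTL and its
#' nearest segregating SNP neighbours.
#'
#' @param pop a [Population-class].
#' @return list with \code{meanR2Snp}, \code{meanR2Qtl}, \code{meanR2SnpQtl},
#'   \code{fractionSegregating}.
#' @export
ldSummary <- function(pop) {
  lc <- lociTable(pop)
  freq <- alleleFreqs(pop, lc$locus)
  seg <- freq > 0 & freq < 1
  consec <- function(type) {
    keep <- lc[seg & lc$type %in% type, ]
    a <- integer(0); b <- integer(0)
    for (ch in unique(keep$chrom)) {
      l <- keep$locus[keep$chrom == ch]
      if (length(l) > 1L) { a <- c(a, l[-length(l)]); b <- c(b, l[-1L]) }
    }
    if (!length(a)) return(NA_real_)
    mean(cpp_pair_r2(pop@haps, a, b), na.rm = TRUE)
  }
  qtlType <- if (any(lc$type == "qtl")) "qtl" else "candidate"
  snpQtl <- function() {
    snps <- lc[seg & lc$type == "snp", ]
    qtls <- lc[seg & lc$type == qtlType, ]
    a <- integer(0); b <- integer(0)
    for (ch in intersect(unique(qtls$chrom), unique(snps$chrom))) {
      q <- qtls[qtls$chrom == ch, ]
      s <- snps[snps$chrom == ch, ]
      for (i in seq_len(nrow(q))) {
        below <- s$locus[s$posCM < q$posCM[i]]
        above <- s$locus[s$posCM > q$posCM[i]]
        if (length(below)) { a <- c(a, q$locus[i]); b <- c(b, below[length(below)]) }
        if (length(above)) { a <- c(a, q$locus[i]); b <- c(b, above[1L]) }
      }
    }
    if (!length(a)) return(NA_real_)
    mean(cpp_pair_r2(pop@haps, a, b), na.rm = TRUE)
  }
  list(meanR2Snp = consec("snp"), meanR2Qtl = consec(qtlType),
       meanR2SnpQtl = snpQtl(), fractionSegregating = mean(seg))
}

#' Loci monomorphic in a population
#'
#' @param pop a [Population-class].
#' @return named logical over all loci.
#' @export
monomorphicLoci <- function(pop) {
  freq <- alleleFreqs(pop, lociTable(pop)$locus)
  freq == 0 | freq == 1
}

#' Sample meiotic gametes from one individual
#'
#' Gametes carry Poisson(chromosome length / 100 cM) crossovers per
#' chromosome at uniform positions without interference, with independent
#' assortment across chromosomes.
#'
#' @param pop a [Population-class].
#' @param individual pedigree row index of the parent.
#' @param n number of gametes.
#' @return raw matrix, loci x n.
#' @export
meiosis <- function(pop, individual, n = 1L) {
  blocks <- chromBlocks(pop@map)
  cpp_gametes(pop@haps, as.integer(individual), as.integer(n), blocks$start,
              blocks$end, blocks$pos, blocks$len)
}
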