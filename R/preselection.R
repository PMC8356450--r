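#' Split extreme-phenotype subpopulations
#'
#' Ranks the genotyped-and-phenotyped training individuals on phenotype
#' (stable tie-break by id) and returns the bottom and top
#' \code{floor(fraction * n)} as the two subpopulations between which F_ST is
#' computed.
#'
#' @param phen named numeric phenotypes of the genotyped training
#'   individuals.
#' @param fraction tail fraction per subpopulation, in (0, 0.5).
#' @return list with \code{lowIds}, \code{highIds}, \code{fraction}.
#' @export
splitExtremes <- function(phen, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 0.5)
    stop("fraction must lie strictly between 0 and 0.5")
  phen <- phen[!is.na(phen)]
  k <- floor(fraction * length(phen))
  if (k < 1L) stop("tail of size 0: need at least ", ceiling(1 / fraction),
                   " phenotyped individuals")
  ids <- names(phen)[order(phen, as.numeric(names(phen)))]
  list(lowIds = as.integer(ids[seq_len(k)]),
       highIds = as.integer(rev(ids)[seq_len(k)]), fraction = fraction)
}

#' Nei F_ST scores between two subpopulations
#'
#' F_ST = (H_T - H_S) / H_T per SNP, with H_T = 2 p_T q_T from the pooled
#' allele frequency and H_S the subpopulation-size-weighted mean of the
#' subpopulation heterozygosities 2 p_Si q_Si. SNPs monomorphic in the pooled
#' sample (H_T = 0) score 0.
#'
#' @param geno 0/1/2 genotype matrix (individuals x loci, ids as rownames).
#' @param split list from [splitExtremes()] (or any \code{lowIds} /
#'   \code{highIds} pair present in \code{geno}).
#' @return data.frame with one row per locus: \code{snp}, \code{pT},
#'   \code{hT}, \code{hS}, \code{fst}.
#' @export
fstScores <- function(geno, split) {
  i1 <- match(as.character(split$lowIds), rownames(geno))
  i2 <- match(as.character(split$highIds), rownames(geno))
  if (!length(i1) || !length(i2) || anyNA(i1) || anyNA(i2))
    stop("subpopulation individuals missing from the genotype matrix")
  n1 <- length(i1); n2 <- length(i2)
  p1 <- colMeans(geno[i1, , drop = FALSE]) / 2
  p2 <- colMeans(geno[i2, , drop = FALSE]) / 2
  pT <- (n1 * p1 + n2 * p2) / (n1 + n2)
  hT <- 2 * pT * (1 - pT)
  hS <- (n1 * 2 * p1 * (1 - p1) + n2 * 2 * p2 * (1 - p2)) / (n1 + n2)
  fst <- ifelse(hT > 0, (hT - hS) / hT, 0)
  data.frame(snp = as.integer(colnames(geno)), pT = pT, hT = hT, hS = hS,
             fst = fst, row.names = NULL)
}

#' Rank loci on a criterion and select the top k
#'
#' Descending order on the score with a deterministic tie-break by
#' (chromosome, position).
#'
#' @param scores named numeric scores (names are locus ids), e.g. F_ST or
#'   absolute back-solved effects.
#' @param k subset size.
#' @param map a [GenomeMap-class] or [Population-class] supplying the
#'   tie-break coordinates.
#' @return integer locus ids of the selected subset, in rank order.
#' @export
rankAndSelect <- function(scores, k, map) {
  if (k <= 0) stop("k must be positive")
  if (k > length(scores)) stop("k exceeds the number of scored loci")
  lc <- lociTable(map)
  idx <- match(as.integer(names(scores)), lc$locus)
  ord <- order(-scores, lc$chrom[idx], lc$posCM[idx])
  as.integer(names(scores)[ord][seq_len(k)])
}

#' Random marker subset
#'
#' Uniform sampling without replacement from the panel.
#'
#' @param snps integer locus ids of the full panel.
#' @param k subset size.
#' @return integer locus ids.
#' @export
randomSubset <- function(snps, k) {
  if (k > length(snps)) stop("k exceeds the panel size")
  sample(snps, k)
}

#' Exclusion panel: full panel minus extreme unlinked markers
#'
#' Removes the top- or bottom-k truth-unlinked (LQ) markers, ranked on the
#' given scores, from the full panel.
#'
#' @param snps integer locus ids of the full panel.
#' @param labels named truth classes from [truthLabels()].
#' @param scores named numeric scores covering the LQ markers.
#' @param k number of unlinked markers to exclude.
#' @param end \code{"top"} (largest scores) or \code{"bottom"}.
#' @param map map for the rank tie-break.
#' @return integer locus ids of the reduced panel.
#' @export
buildExclusionPanel <- function(snps, labels, scores, k,
                                end = c("top", "bottom"), map) {
  end <- match.arg(end)
  lq <- snps[labels[as.character(snps)] == "LQ"]
  if (k > length(lq)) stop("k exceeds the number of unlinked markers")
  if (k == 0L) return(snps)
  s <- scores[as.character(lq)]
  if (anyNA(s)) stop("scores missing for some unlinked markers")
  if (end == "bottom") s <- -s
  drop <- rankAndSelect(setNames(as.numeric(s), lq), k, map)
  setdiff(snps, drop)
}
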