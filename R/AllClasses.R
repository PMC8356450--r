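#' GenomeMap: layout of SNP and QTL loci on a linkage map
#'
#' Holds one row per locus, sorted by (chromosome, position in cM), plus the
#' generating configuration. Locus types are \code{"snp"} (marker panel),
#' \code{"qtl"} (causal locus with an assigned effect) and \code{"candidate"}
#' (potential QTL position laid out before effects are assigned; candidates
#' that end up unused are excluded from both the marker panel and the trait).
#'
#' @slot loci data.frame with columns \code{locus} (integer row id),
#'   \code{chrom}, \code{posCM}, \code{type}, \code{class} (\code{"HQ"} for
#'   SNPs on a QTL-bearing chromosome, \code{"LQ"} otherwise, \code{NA} for
#'   non-SNP loci).
#' @slot config the [genomeConfig()] list used to build the map.
#' @export
setClass("GenomeMap", representation(loci = "data.frame", config = "list"))

setValidity("GenomeMap", function(object) {
  lc <- object@loci
  need <- c("locus", "chrom", "posCM", "type", "class")
  if (!all(need %in% names(lc)))
    return(paste("loci must have columns", paste(need, collapse = ", ")))
  if (is.unsorted(order(lc$chrom, lc$posCM)) &&
      any(diff(order(lc$chrom, lc$posCM)) < 0))
    return("loci must be sorted by (chrom, posCM)")
  if (!all(lc$type %in% c("snp", "snp_cand", "qtl", "candidate")))
    return("unknown locus type")
  TRUE
})

#' Population: haplotypes, pedigree, trait values and genotyping flags
#'
#' One column pair of the raw haplotype matrix per individual (allele codes
#' 0/1 per locus, loci as in the map). The pedigree uses 0 for unknown
#' parents and is sorted so parents precede offspring.
#'
#' @slot haps raw matrix, loci x (2 x individuals).
#' @slot map a [GenomeMap-class].
#' @slot pedigree data.frame with columns \code{id}, \code{sire}, \code{dam},
#'   \code{generation}, \code{sex} (\code{"M"}/\code{"F"}/\code{NA}).
#' @slot tbv numeric true breeding value per individual (NA until QTL effects
#'   are assigned).
#' @slot phenotype numeric, NA for unphenotyped individuals.
#' @slot genotyped logical per individual.
#' @slot qtlEffects named numeric, allele-substitution effect per active QTL
#'   locus (names are locus row ids).
#' @slot ldSummary list of realized linkage-disequilibrium summaries.
#' @export
setClass("Population", representation(
  haps = "matrix", map = "GenomeMap", pedigree = "data.frame",
  tbv = "numeric", phenotype = "numeric", genotyped = "logical",
  qtlEffects = "numeric", ldSummary = "list"))

setValidity("Population", function(object) {
  n <- nrow(object@pedigree)
  if (!is.raw(object@haps)) return("haps must be a raw matrix")
  if (ncol(object@haps) != 2L * n)
    return("haps must have two columns per pedigree individual")
  if (nrow(object@haps) != nrow(object@map@loci))
    return("haps rows must match map loci")
  if (length(object@tbv) != n || length(object@phenotype) != n ||
      length(object@genotyped) != n)
    return("tbv/phenotype/genotyped length must match pedigree")
  ped <- object@pedigree
  pos <- match(ped$sire, ped$id)
  if (any(!is.na(pos) & pos >= seq_len(n))) return("sire after offspring")
  pos <- match(ped$dam, ped$id)
  if (any(!is.na(pos) & pos >= seq_len(n))) return("dam after offspring")
  TRUE
})

#' RelationshipMatrix: symmetric individual-by-individual relationships
#'
#' @slot values symmetric numeric matrix with ids as dimnames.
#' @slot role one of \code{"A"}, \code{"A22"}, \code{"G_marker"},
#'   \code{"G_QTL"}, \code{"G_blended"}, \code{"H_inverse"}.
#' @slot ids integer individual ids indexing rows/columns.
#' @slot alleleFreqs numeric per-locus frequencies used in centering (empty
#'   for pedigree-based matrices).
#' @slot markerSet integer locus ids of the marker subset used (empty for
#'   pedigree-based matrices).
#' @export
setClass("RelationshipMatrix", representation(
  values = "matrix", role = "character", ids = "integer",
  alleleFreqs = "numeric", markerSet = "integer"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (length(object@ids) != nrow(v)) return("ids must match dimension")
  if (nrow(v) && max(abs(v - t(v))) > 1e-8 * (1 + max(abs(v))))
    return("matrix must be symmetric")
  if (!object@role %in% c("A", "A22", "G_marker", "G_QTL", "G_blended",
                          "H_inverse"))
    return("unknown role")
  TRUE
})

setMethod("show", "GenomeMap", function(object) {
  lc <- object@loci
  cat("GenomeMap:", length(unique(lc$chrom)), "chromosomes,",
      sum(lc$type == "snp"), "SNPs,", sum(lc$type == "qtl"), "QTL,",
      sum(lc$type == "candidate"), "candidate QTL positions\n")
})

setMethod("show", "Population", function(object) {
  ped <- object@pedigree
  cat("Population:", nrow(ped), "individuals in",
      length(unique(ped$generation)), "generation(s);",
      sum(object@genotyped), "genotyped,",
      sum(!is.na(object@phenotype)), "phenotyped\n")
  show(object@map)
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix [", object@role, "]: ", nrow(object@values), " x ",
      ncol(object@values), sep = "")
  if (length(object@markerSet))
    cat(", ", length(object@markerSet), " loci", sep = "")
  cat("\n")
})

#' @describeIn GenomeMap-class locus table accessor
#' @param x a GenomeMap or Population
#' @export
lociTable <- function(x) {
  if (is(x, "Population")) x@map@loci else x@loci
}

#' @describeIn Population-class pedigree accessor
#' @export
pedigree <- function(x) x@pedigree

#' @describeIn Population-class phenotype accessor
#' @export
phenotypes <- function(x) setNames(x@phenotype, x@pedigree$id)

#' @describeIn Population-class true-breeding-value accessor
#' @export
trueBV <- function(x) setNames(x@tbv, x@pedigree$id)

#' @describeIn Population-class genotyped-flag accessor
#' @export
isGenotyped <- function(x) setNames(x@genotyped, x@pedigree$id)

#' @describeIn Population-class QTL effect accessor
#' @export
qtlEffects <- function(x) x@qtlEffects

#' @describeIn RelationshipMatrix-class numeric matrix accessor (also accepts
#'   a plain matrix, returned as is)
#' @export
relValues <- function(x) if (is(x, "RelationshipMatrix")) x@values else x

#' @describeIn RelationshipMatrix-class id accessor
#' @export
relIds <- function(x) x@ids

#' @describeIn RelationshipMatrix-class role accessor
#' @export
relRole <- function(x) x@role
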