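#' Pedigree numerator relationship matrix (A)
#'
#' Builds A by the tabular method. Unknown parents (0 or NA) are treated as
#' unrelated, non-inbred founders; the pedigree must list parents before
#' offspring.
#'
#' @param ped data.frame with columns \code{id}, \code{sire}, \code{dam}
#'   (0/NA for unknown), in parents-first order.
#' @return a [RelationshipMatrix-class] with role \code{"A"}.
#' @export
buildA <- function(ped) {
  id <- ped$id
  s <- match(ped$sire, id, nomatch = 0L)
  d <- match(ped$dam, id, nomatch = 0L)
  known <- !is.na(ped$sire) & ped$sire != 0L
  if (any(known & s == 0L)) stop("sire missing from pedigree")
  knownD <- !is.na(ped$dam) & ped$dam != 0L
  if (any(knownD & d == 0L)) stop("dam missing from pedigree")
  A <- cpp_tabular_A(s, d)
  dimnames(A) <- list(id, id)
  new("RelationshipMatrix", values = A, role = "A", ids = as.integer(id),
      alleleFreqs = numeric(0), markerSet = integer(0))
}

#' Subset a pedigree relationship matrix to the genotyped individuals (A22)
#'
#' @param A a [RelationshipMatrix-class] with role \code{"A"}.
#' @param ids genotyped individual ids.
#' @return a [RelationshipMatrix-class] with role \code{"A22"}.
#' @export
subsetA22 <- function(A, ids) {
  idx <- match(ids, A@ids)
  if (anyNA(idx)) stop("ids missing from A")
  new("RelationshipMatrix", values = A@values[idx, idx, drop = FALSE],
      role = "A22", ids = as.integer(ids), alleleFreqs = numeric(0),
      markerSet = integer(0))
}

#' VanRaden genomic relationship matrix
#'
#' G = ZZ' / (2 * sum p_i (1 - p_i)) with Z the 0/1/2 genotype codes centered
#' by twice the allele frequency. Loci monomorphic at the supplied
#' frequencies contribute nothing to the numerator and are excluded from the
#' denominator sum.
#'
#' @param geno numeric matrix of 0/1/2 genotype codes, individuals x loci,
#'   with locus ids as column names and individual ids as row names.
#' @param markerSet locus ids of the subset to use (default: all columns).
#' @param freqs named per-locus allele frequencies used for centering
#'   (default: observed column means / 2).
#' @param role stored role tag, \code{"G_marker"} or \code{"G_QTL"}.
#' @return a [RelationshipMatrix-class].
#' @export
buildG <- function(geno, markerSet = colnames(geno), freqs = NULL,
                   role = "G_marker") {
  markerSet <- as.character(markerSet)
  if (!length(markerSet)) stop("marker subset is empty")
  if (anyNA(match(markerSet, colnames(geno))))
    stop("marker subset contains loci absent from the genotype matrix")
  X <- geno[, markerSet, drop = FALSE]
  if (anyNA(X) || any(X < 0 | X > 2 | X != round(X)))
    stop("genotype codes must be 0, 1 or 2")
  if (is.null(freqs)) freqs <- colMeans(X) / 2
  p <- freqs[markerSet]
  if (anyNA(p)) stop("freqs missing for some subset loci")
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all subset loci are monomorphic")
  Z <- sweep(X[, poly, drop = FALSE], 2L, 2 * p[poly], "-")
  den <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / den
  new("RelationshipMatrix", values = G, role = role,
      ids = as.integer(rownames(geno)), alleleFreqs = p,
      markerSet = as.integer(markerSet))
}

#' Genomic relationship matrix from QTL genotypes
#'
#' The VanRaden construction of [buildG()] applied to the causal loci.
#'
#' @inheritParams buildG
#' @return a [RelationshipMatrix-class] with role \code{"G_QTL"}.
#' @export
buildGqtl <- function(geno, markerSet = colnames(geno), freqs = NULL) {
  buildG(geno, markerSet, freqs, role = "G_QTL")
}

#' Blend a genomic relationship matrix with pedigree expectations
#'
#' G* = (1 - tau) G + tau A22. A small pedigree weight guarantees a
#' positive-definite, invertible matrix for the single-step system and for
#' SNP-effect back-solving.
#'
#' @param G,A22 [RelationshipMatrix-class] (or plain matrices) on the same
#'   individuals in the same order.
#' @param tau pedigree weight in [0, 1].
#' @return a [RelationshipMatrix-class] with role \code{"G_blended"}.
#' @export
blendG <- function(G, A22, tau = 0.05) {
  g <- relValues(G); a <- relValues(A22)
  if (!all(dim(g) == dim(a))) stop("dimension mismatch between G and A22")
  ids <- if (is(G, "RelationshipMatrix")) G@ids else
    as.integer(rownames(g) %||% seq_len(nrow(g)))
  new("RelationshipMatrix", values = (1 - tau) * g + tau * a,
      role = "G_blended", ids = ids,
      alleleFreqs = if (is(G, "RelationshipMatrix")) G@alleleFreqs else numeric(0),
      markerSet = if (is(G, "RelationshipMatrix")) G@markerSet else integer(0))
}

# Inverse of a symmetric positive-definite matrix via Cholesky; `what` names
# the matrix in the error raised on failure.
pdInverse <- function(M, what = "matrix") {
  R <- tryCatch(chol(relValues(M)),
                error = function(e) stop(what, " is singular or not positive ",
                                         "definite; blend with A22 ",
                                         "(blendG) before inverting",
                                         call. = FALSE))
  chol2inv(R)
}

#' Inverse of the single-step relationship matrix H
#'
#' H^-1 = A^-1 plus (G*^-1 - A22^-1) added on the genotyped block, the
#' standard single-step GBLUP combination of pedigree and genomic
#' information.
#'
#' @param A a [RelationshipMatrix-class] with role \code{"A"} over all
#'   pedigree individuals.
#' @param Gstar blended genomic matrix over the genotyped individuals (see
#'   [blendG()]).
#' @param genotypedIds ids of the genotyped individuals (defaults to
#'   \code{Gstar}'s ids).
#' @return a [RelationshipMatrix-class] with role \code{"H_inverse"} over all
#'   pedigree individuals.
#' @export
buildHinv <- function(A, Gstar, genotypedIds = NULL) {
  if (is.null(genotypedIds))
    genotypedIds <- if (is(Gstar, "RelationshipMatrix")) Gstar@ids else
      as.integer(rownames(relValues(Gstar)))
  Ainv <- pdInverse(A, "A")
  H <- Ainv
  if (length(genotypedIds)) {
    idx <- match(genotypedIds, A@ids)
    if (anyNA(idx)) stop("genotyped ids missing from A")
    A22inv <- pdInverse(subsetA22(A, genotypedIds), "A22")
    Ginv <- pdInverse(Gstar, "G*")
    H[idx, idx] <- H[idx, idx] + Ginv - A22inv
  }
  dimnames(H) <- dimnames(relValues(A))
  new("RelationshipMatrix", values = H, role = "H_inverse", ids = A@ids,
      alleleFreqs = numeric(0), markerSet = integer(0))
}

#' Write / read a relationship matrix as id-id-value triplets
#'
#' Plain-text lower-triangle triplet format (\code{id_i id_j value}, i >= j)
#' for interoperability with BLUPF90-style tools.
#'
#' @param R a [RelationshipMatrix-class].
#' @param path file path.
#' @export
writeGTriplet <- function(R, path) {
  v <- relValues(R)
  ids <- R@ids
  idx <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
  write.table(data.frame(ids[idx[, 1L]], ids[idx[, 2L]], v[idx]), path,
              row.names = FALSE, col.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname writeGTriplet
#' @param role role tag for the reconstructed matrix.
#' @export
readGTriplet <- function(path, role = "G_marker") {
  tr <- read.table(path, col.names = c("i", "j", "x"))
  ids <- sort(unique(c(tr$i, tr$j)))
  n <- length(ids)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  ii <- match(tr$i, ids); jj <- match(tr$j, ids)
  v[cbind(ii, jj)] <- tr$x
  v[cbind(jj, ii)] <- tr$x
  new("RelationshipMatrix", values = v, role = role, ids = as.integer(ids),
      alleleFreqs = numeric(0), markerSet = integer(0))
}
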