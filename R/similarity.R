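# Agreement diagnostics between marker- and QTL-based genomic relationships.
# All metrics work on the off-diagonal unique pairs of a designated
# individual set (the genotyped training individuals in the pipeline), and
# standard deviations are taken over that same pair set.

# Align three relationship matrices on one id set and return the pair
# vectors.
msPairs <- function(GM, GQTL, A22, ids = NULL) {
  gm <- relValues(GM); gq <- relValues(GQTL); a <- relValues(A22)
  if (is.null(ids)) {
    idx <- seq_len(nrow(gm))
    if (!all(dim(gm) == dim(gq)) || !all(dim(gm) == dim(a)))
      stop("matrices must be on identical id sets")
    list(gm = gm[lower.tri(gm)], gq = gq[lower.tri(gq)], a = a[lower.tri(a)])
  } else {
    pick <- function(M, obj) {
      i <- if (is(obj, "RelationshipMatrix")) match(ids, obj@ids) else
        match(as.character(ids), rownames(M))
      if (anyNA(i)) stop("ids missing from a relationship matrix")
      M[i, i, drop = FALSE]
    }
    gm <- pick(gm, GM); gq <- pick(gq, GQTL); a <- pick(a, A22)
    list(gm = gm[lower.tri(gm)], gq = gq[lower.tri(gq)], a = a[lower.tri(a)])
  }
}

#' Correlation between marker- and QTL-based relationship matrices
#'
#' Pearson correlation over off-diagonal unique pairs. The non-centered
#' correlation reflects total QTL similarity (expected relationship plus
#' Mendelian sampling); the centered variant subtracts the pedigree
#' expectation A22 from both matrices first and isolates the
#' Mendelian-sampling component.
#'
#' @param GM,GQTL marker- and QTL-based [RelationshipMatrix-class] (or plain
#'   matrices) on identical individuals.
#' @param centered subtract A22 before correlating?
#' @param A22 pedigree expectations, required when \code{centered}.
#' @param ids optional id subset defining the pair set.
#' @return correlation, or NA (with a warning) when a matrix is constant
#'   over the pair set.
#' @export
matrixCorrelation <- function(GM, GQTL, centered = FALSE, A22 = NULL,
                              ids = NULL) {
  if (centered && is.null(A22)) stop("A22 required for the centered variant")
  pr <- if (is.null(A22)) {
    p <- msPairs(GM, GQTL, GM, ids); p$a <- 0; p
  } else msPairs(GM, GQTL, A22, ids)
  x <- if (centered) pr$gm - pr$a else pr$gm
  y <- if (centered) pr$gq - pr$a else pr$gq
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant matrix; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Directional Mendelian-sampling agreement
#'
#' For each pair, the magnitude of the marker Mendelian-sampling deviation in
#' matrix-standard-deviation units, |g_m - a22| / sd(G_M), signed positive
#' when the marker and QTL deviations from the expected relationship share a
#' direction and negative otherwise. Pairs whose QTL deviation is numerically
#' zero (|g_qtl - a22| < eps * sd(G_QTL)) are assigned the positive sign.
#'
#' @inheritParams matrixCorrelation
#' @param eps relative threshold declaring a QTL deviation zero.
#' @return list with \code{values} (signed reals per pair),
#'   \code{positiveFraction}, and \code{nNearZero}.
#' @export
directionalMS <- function(GM, GQTL, A22, ids = NULL, eps = 1e-8) {
  pr <- msPairs(GM, GQTL, A22, ids)
  sdm <- sd(pr$gm)
  if (sdm == 0) stop("sd(G_M) over the pair set is zero")
  dm <- pr$gm - pr$a
  dq <- pr$gq - pr$a
  nearZero <- abs(dq) < eps * sd(pr$gq)
  sgn <- ifelse(nearZero | sign(dm) == sign(dq) | dm == 0, 1, -1)
  list(values = sgn * abs(dm) / sdm,
       positiveFraction = mean(sgn > 0), nNearZero = sum(nearZero))
}

#' Mendelian-sampling error (%)
#'
#' 100 * |(m - q) / q| per pair, where m and q are the marker and QTL
#' deviations from the expected relationship, each standardized by its own
#' matrix standard deviation over the pair set. Pairs with numerically zero
#' QTL deviation are excluded (and counted). Values below 100 mean the
#' marker relationship approximates the QTL relationship more closely than
#' the pedigree expectation does.
#'
#' @inheritParams directionalMS
#' @return list with \code{values} (percent, per included pair) and
#'   \code{nExcluded}.
#' @export
msErrorPct <- function(GM, GQTL, A22, ids = NULL, eps = 1e-8) {
  pr <- msPairs(GM, GQTL, A22, ids)
  sdm <- sd(pr$gm); sdq <- sd(pr$gq)
  if (sdm == 0 || sdq == 0) stop("zero matrix sd over the pair set")
  dq <- pr$gq - pr$a
  keep <- abs(dq) >= eps * sdq
  if (!any(keep)) stop("all pairs have zero QTL Mendelian sampling")
  m <- (pr$gm[keep] - pr$a[keep]) / sdm
  q <- dq[keep] / sdq
  list(values = 100 * abs((m - q) / q), nExcluded = sum(!keep))
}

#' Overlap of a marker subset with the truth-linked class
#'
#' @param subset integer locus ids.
#' @param labels named truth classes from [truthLabels()].
#' @return percentage of subset markers labelled \code{"HQ"}.
#' @export
overlapPct <- function(subset, labels) {
  if (!length(subset)) stop("empty subset")
  cls <- labels[as.character(subset)]
  if (anyNA(cls)) stop("labels missing for some subset markers")
  100 * mean(cls == "HQ")
}

#' Genetic variance explained by a marker subset
#'
#' A QTL counts as explained when at least one subset marker has squared
#' Pearson correlation of allele counts (r2) above the threshold with it,
#' computed in the reference individuals. The explained fraction weights
#' each tagged QTL by its variance contribution 2 p (1 - p) a^2.
#'
#' @param subset integer SNP locus ids.
#' @param qtlGeno 0/1/2 dosages of the QTL in the reference individuals
#'   (columns named by locus id).
#' @param snpGeno 0/1/2 dosages of the subset SNPs in the same individuals.
#' @param effects named QTL allele-substitution effects.
#' @param r2Threshold tagging threshold.
#' @return list with \code{explainedFraction}, \code{perQtl} (logical) and
#'   \code{nMonomorphic} (QTL excluded from the totals, with a warning).
#' @export
varianceExplained <- function(subset, qtlGeno, snpGeno, effects,
                              r2Threshold = 0.9) {
  snpGeno <- snpGeno[, as.character(subset), drop = FALSE]
  p <- colMeans(qtlGeno) / 2
  mono <- p == 0 | p == 1
  if (any(mono))
    warning(sum(mono), " monomorphic QTL excluded from variance totals")
  a <- effects[colnames(qtlGeno)]
  w <- 2 * p * (1 - p) * a^2
  polySnp <- apply(snpGeno, 2L, sd) > 0
  tagged <- rep(FALSE, ncol(qtlGeno))
  if (any(polySnp) && any(!mono)) {
    r2 <- suppressWarnings(cor(qtlGeno[, !mono, drop = FALSE],
                               snpGeno[, polySnp, drop = FALSE]))^2
    tagged[!mono] <- apply(r2, 1L, max, na.rm = TRUE) > r2Threshold
  }
  perQtl <- setNames(tagged, colnames(qtlGeno))
  list(explainedFraction = sum(w[!mono & tagged]) / sum(w[!mono]),
       perQtl = perQtl, nMonomorphic = sum(mono))
}

#' Concordance between F_ST scores and absolute estimated effects
#'
#' Pearson correlation of the two preselection statistics within the
#' truth-linked (HQ) and truth-unlinked (LQ) marker classes, plus the
#' scatter table with top-k inclusion thresholds for both criteria.
#'
#' @param fst named F_ST scores per SNP.
#' @param absEffect named absolute back-solved effects per SNP.
#' @param labels named truth classes.
#' @param k subset size defining the inclusion thresholds (optional).
#' @return list with \code{corHQ}, \code{corLQ}, \code{table} (snp, fst,
#'   absEffect, class) and \code{thresholds}.
#' @export
scoreEffectConcordance <- function(fst, absEffect, labels, k = NULL) {
  snps <- names(fst)
  tab <- data.frame(snp = as.integer(snps), fst = as.numeric(fst),
                    absEffect = as.numeric(absEffect[snps]),
                    class = labels[snps], row.names = NULL)
  corClass <- function(cls) {
    d <- tab[tab$class == cls, ]
    if (nrow(d) < 3L || sd(d$fst) == 0 || sd(d$absEffect) == 0)
      return(NA_real_)
    cor(d$fst, d$absEffect)
  }
  thr <- if (!is.null(k) && k <= nrow(tab)) {
    list(fst = sort(tab$fst, decreasing = TRUE)[k],
         absEffect = sort(tab$absEffect, decreasing = TRUE)[k])
  } else NULL
  list(corHQ = corClass("HQ"), corLQ = corClass("LQ"), table = tab,
       thresholds = thr)
}
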