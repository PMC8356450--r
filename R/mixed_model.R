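# Mixed-model equations for a mean-plus-animal model. Variance components
# are taken as known (the simulation truth), so lambda = varE/varG.

# Solve [n 1'W; W'1 W'W + lambda*Kinv] [mu; u] = [sum(y); W'y].
# Dense Cholesky up to `denseLimit` equations, Jacobi-preconditioned
# conjugate gradient above (tolerance on the relative residual).
mmeSolve <- function(Kinv, phen, lambda, denseLimit = 8000L, tol = 1e-10) {
  n <- nrow(Kinv)
  w <- as.numeric(!is.na(phen))
  if (sum(w) < 1) stop("singular system: no phenotype records")
  y <- ifelse(is.na(phen), 0, phen)
  C <- lambda * Kinv
  diag(C) <- diag(C) + w
  C <- rbind(c(sum(w), w), cbind(w, C))
  rhs <- c(sum(y), w * y)
  sol <- if (n + 1L <= denseLimit) {
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) solve(C, rhs) else backsolve(ch, forwardsolve(t(ch), rhs))
  } else {
    cgSolve(C, rhs, tol = tol)
  }
  list(mu = sol[1L], u = sol[-1L])
}

#' Conjugate-gradient solver for symmetric positive-definite systems
#'
#' Jacobi (diagonal) preconditioning; iterates until the relative residual
#' drops below \code{tol}.
#'
#' @param C symmetric positive-definite matrix.
#' @param b right-hand side.
#' @param tol relative-residual tolerance.
#' @param maxit iteration cap.
#' @return solution vector.
#' @export
cgSolve <- function(C, b, tol = 1e-10, maxit = 20L * length(b)) {
  x <- numeric(length(b))
  r <- b
  Minv <- 1 / diag(C)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  for (it in seq_len(maxit)) {
    Cp <- drop(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    if (sqrt(sum(r^2)) <= tol * bn) break
    z <- Minv * r
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  x
}

#' Pedigree BLUP (animal model with the A matrix)
#'
#' Fits the mean-plus-animal mixed model with the pedigree numerator
#' relationship matrix. Unphenotyped individuals receive parent-average
#' propagated EBVs through the A-inverse structure.
#'
#' @param phen numeric phenotype vector aligned with the pedigree rows (NA =
#'   no record).
#' @param ped pedigree data.frame (\code{id}, \code{sire}, \code{dam},
#'   parents-first).
#' @param varG,varE variance components (lambda = varE/varG).
#' @param ... passed to the solver (e.g. \code{denseLimit}).
#' @return data.frame with columns \code{id}, \code{ebv}; the fitted mean is
#'   attached as attribute \code{"mu"}.
#' @export
solveABlup <- function(phen, ped, varG = 0.4, varE = 0.6, ...) {
  A <- buildA(ped)
  fit <- mmeSolve(pdInverse(A, "A"), phen, varE / varG, ...)
  structure(data.frame(id = ped$id, ebv = fit$u), mu = fit$mu)
}

#' Single-step GBLUP
#'
#' Fits the same animal model with the inverse single-step matrix H^-1 in
#' place of A^-1, returning EBVs for every pedigree individual including
#' genotyped, unphenotyped validation animals.
#'
#' @param phen numeric phenotype vector aligned with the pedigree rows.
#' @param ped pedigree data.frame.
#' @param Hinv a [RelationshipMatrix-class] with role \code{"H_inverse"}
#'   (from [buildHinv()]) on the pedigree ids, in order.
#' @param varG,varE variance components.
#' @param ... passed to the solver.
#' @return data.frame with columns \code{id}, \code{ebv}.
#' @export
solveSsgblup <- function(phen, ped, Hinv, varG = 0.4, varE = 0.6, ...) {
  hv <- relValues(Hinv)
  if (is(Hinv, "RelationshipMatrix") && !identical(Hinv@ids,
                                                   as.integer(ped$id)))
    stop("H inverse ids do not match the pedigree")
  if (nrow(hv) != nrow(ped)) stop("H inverse dimension does not match pedigree")
  fit <- mmeSolve(hv, phen, varE / varG, ...)
  structure(data.frame(id = ped$id, ebv = fit$u), mu = fit$mu)
}

#' Back-solve SNP effects from genomic breeding values
#'
#' u = D Z' (Z D Z')^-1 a, with Z the allele-frequency-centered genotype
#' codes of the genotyped training individuals and a their estimated
#' breeding values. With identity weights Z Z' equals the VanRaden G times
#' its denominator, so the inverse is taken on the blended genomic matrix
#' (weight \code{tau} on A22); \code{tau = 0} requires a full-rank Z Z'
#' (e.g. external allele frequencies).
#'
#' @param ebv data.frame (\code{id}, \code{ebv}) or named vector for the
#'   genotyped training individuals.
#' @param geno 0/1/2 genotype matrix of those individuals (rows in the same
#'   order, locus ids as column names).
#' @param freqs named allele frequencies used for centering (default:
#'   observed).
#' @param A22 pedigree relationships of the same individuals, required when
#'   \code{tau > 0}.
#' @param tau blending weight passed to [blendG()].
#' @param weights optional diagonal of D (per polymorphic locus weight).
#' @return data.frame with columns \code{snp}, \code{effect}, \code{weight}
#'   (one row per panel locus; monomorphic loci get effect 0).
#' @export
backsolveSnpEffects <- function(ebv, geno, freqs = NULL, A22 = NULL,
                                tau = 0.05, weights = NULL) {
  a <- if (is.data.frame(ebv)) setNames(ebv$ebv, ebv$id) else ebv
  if (length(a) != nrow(geno)) stop("ebv length does not match genotypes")
  if (is.null(freqs)) freqs <- colMeans(geno) / 2
  p <- freqs[colnames(geno)]
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all loci are monomorphic")
  Z <- sweep(geno[, poly, drop = FALSE], 2L, 2 * p[poly], "-")
  den <- 2 * sum(p[poly] * (1 - p[poly]))
  if (is.null(weights)) {
    G <- tcrossprod(Z) / den
    M <- if (tau > 0) {
      if (is.null(A22)) stop("A22 required for blending (tau > 0)")
      den * relValues(blendG(G, A22, tau))
    } else den * G
  } else {
    if (length(weights) != sum(poly)) stop("one weight per polymorphic locus")
    M <- Z %*% (weights * t(Z))
    if (tau > 0) {
      if (is.null(A22)) stop("A22 required for blending (tau > 0)")
      M <- (1 - tau) * M + tau * den * relValues(A22)
    }
  }
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch))
    stop("Z D Z' is singular; blend with A22 (tau > 0) to back-solve")
  sol <- backsolve(ch, forwardsolve(t(ch), a))
  u <- drop(crossprod(Z, sol))
  if (!is.null(weights)) u <- weights * u
  out <- data.frame(snp = as.integer(colnames(geno)),
                    effect = 0, weight = 0)
  out$effect[poly] <- u
  out$weight[poly] <- if (is.null(weights)) 1 else weights
  out$weight[!poly] <- NA
  out
}

#' Prediction accuracy
#'
#' Pearson correlation between estimated and true breeding values over a
#' validation set.
#'
#' @param ebv data.frame (\code{id}, \code{ebv}) or named vector.
#' @param tbv named numeric true breeding values.
#' @param ids validation individual ids.
#' @return correlation, or NA (with a warning) if either vector has zero
#'   variance.
#' @export
predictionAccuracy <- function(ebv, tbv, ids) {
  e <- if (is.data.frame(ebv)) setNames(ebv$ebv, ebv$id) else ebv
  ids <- as.character(ids)
  e <- e[ids]; t <- tbv[ids]
  ok <- !is.na(e) & !is.na(t)
  if (sum(ok) < 3L) stop("need at least 3 validation individuals")
  if (sd(e[ok]) == 0 || sd(t[ok]) == 0) {
    warning("zero variance; accuracy undefined")
    return(NA_real_)
  }
  cor(e[ok], t[ok])
}
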