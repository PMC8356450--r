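# Independent oracles used to cross-check the implementation.

# Gene-dropping estimate of the numerator relationship a_ij = 2 * kinship.
# Founder alleles get unique labels; each drop transmits one random allele
# per parent. Vectorized over drops.
geneDropA <- function(ped, pairs, ndrops = 1e5) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$id, nomatch = 0L)
  d <- match(ped$dam, ped$id, nomatch = 0L)
  al1 <- matrix(0L, n, ndrops)
  al2 <- matrix(0L, n, ndrops)
  lab <- 0L
  for (i in seq_len(n)) {
    if (s[i] == 0L) {
      al1[i, ] <- lab + 1L; lab <- lab + 1L
    } else {
      pick <- runif(ndrops) < 0.5
      al1[i, ] <- ifelse(pick, al1[s[i], ], al2[s[i], ])
    }
    if (d[i] == 0L) {
      al2[i, ] <- lab + 1L; lab <- lab + 1L
    } else {
      pick <- runif(ndrops) < 0.5
      al2[i, ] <- ifelse(pick, al1[d[i], ], al2[d[i], ])
    }
  }
  apply(pairs, 1L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    ibd <- (al1[i, ] == al1[j, ]) + (al1[i, ] == al2[j, ]) +
      (al2[i, ] == al1[j, ]) + (al2[i, ] == al2[j, ])
    if (i == j) 0.5 * mean(ibd) + 0.5 else 0.5 * mean(ibd)
  })
}

# Minimal two-locus Wright-Fisher simulator: `nrep` independent locus pairs
# at recombination fraction `cfrac`, through the diploid size schedule
# `sizes` (generation 0 initialized at frequency 0.5, independent loci).
# Returns the mean r^2 over segregating pairs in the final generation.
wfTwoLocusR2 <- function(sizes, cfrac, nrep) {
  r2 <- numeric(0)
  for (rep in seq_len(nrep)) {
    nh <- 2L * sizes[1L]
    hapA <- sample(0:1, nh, replace = TRUE)
    hapB <- sample(0:1, nh, replace = TRUE)
    for (g in seq_len(length(sizes) - 1L)) {
      n <- sizes[g + 1L]
      parent <- cbind(sample.int(length(hapA) / 2L, 2L * n, replace = TRUE))
      h1 <- 2L * parent - 1L
      h2 <- 2L * parent
      pickA <- runif(2L * n) < 0.5
      recomb <- runif(2L * n) < cfrac
      pickB <- xor(pickA, recomb)
      hapA <- ifelse(pickA, hapA[h1], hapA[h2])
      hapB <- ifelse(pickB, hapB[h1], hapB[h2])
    }
    pa <- mean(hapA); pb <- mean(hapB)
    if (pa > 0 && pa < 1 && pb > 0 && pb < 1) {
      D <- mean(hapA * hapB) - pa * pb
      r2 <- c(r2, D^2 / (pa * (1 - pa) * pb * (1 - pb)))
    }
  }
  r2
}

# Dense single-step H assembled from its closed-form blocks (genotyped block
# = G, ungenotyped conditioned on it through the pedigree).
denseH <- function(A, G, gidx) {
  n <- nrow(A)
  u <- setdiff(seq_len(n), gidx)
  H <- A
  A22i <- solve(A[gidx, gidx])
  H[u, u] <- A[u, u] +
    A[u, gidx] %*% A22i %*% (G - A[gidx, gidx]) %*% A22i %*% A[gidx, u]
  H[u, gidx] <- A[u, gidx] %*% A22i %*% G
  H[gidx, u] <- t(H[u, gidx])
  H[gidx, gidx] <- G
  H
}
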