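# Internal helpers shared across modules.

# Derive reproducible child seeds from a master seed. One stream per
# replicate/stage keeps stages independent while the whole experiment stays a
# pure function of the master seed.
deriveSeeds <- function(master, n) {
  stopifnot(length(master) == 1L, is.finite(master))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Chromosome block boundaries of a locus table for the C++ meiosis kernel:
# 0-based start (inclusive) and end (exclusive) per chromosome.
chromBlocks <- function(map) {
  lc <- lociTable(map)
  chroms <- sort(unique(lc$chrom))
  start <- integer(length(chroms))
  end <- integer(length(chroms))
  for (i in seq_along(chroms)) {
    idx <- which(lc$chrom == chroms[i])
    start[i] <- min(idx) - 1L
    end[i] <- max(idx)
  }
  cfg <- if (is(map, "GenomeMap")) map@config else map@map@config
  list(start = start, end = end, pos = lc$posCM,
       len = rep(cfg$chromLengthCM, length(chroms)))
}

# Genotype dosage matrix (individuals x loci) for the given individual row
# indices and locus row ids.
dosageMatrix <- function(pop, loci, individuals = seq_len(nrow(pop@pedigree))) {
  m <- cpp_dosage(pop@haps, as.integer(loci), as.integer(individuals))
  dimnames(m) <- list(pop@pedigree$id[individuals], loci)
  m
}

# Allele frequencies of the given loci over the given individuals.
alleleFreqs <- function(pop, loci, individuals = seq_len(nrow(pop@pedigree))) {
  h <- if (identical(as.integer(individuals), seq_len(nrow(pop@pedigree)))) {
    pop@haps
  } else {
    cols <- as.integer(rbind(2L * individuals - 1L, 2L * individuals))
    pop@haps[, cols, drop = FALSE]
  }
  setNames(cpp_allele_freq(h, as.integer(loci)), loci)
}

# Off-diagonal unique-pair values of a symmetric matrix restricted to `idx`.
pairValues <- function(M, idx = seq_len(nrow(M))) {
  M <- relValues(M)[idx, idx, drop = FALSE]
  M[lower.tri(M)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
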