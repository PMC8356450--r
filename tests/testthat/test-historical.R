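# Drift, LD buildup and meiosis of the historical simulator.

test_that("zero generations of history leave initialization untouched", {
  set.seed(11)
  map <- buildGenomeMap(genomeConfig(nChromosomes = 4L, nSnpsTotal = 200L,
                                     nQtl = 0L))
  pop <- simulateHistorical(map, historicalConfig(
    nGenerations = 0L, bottleneckGeneration = -1L, baseSize = 80L,
    finalSize = 80L))
  freq <- colMeans(FstPresel:::dosageMatrix(pop, lociTable(pop)$locus)) / 2
  expect_equal(mean(freq), 0.5, tolerance = 0.02)
  # independent starting haplotypes: near-zero LD between chromosomes
  expect_lt(mean(cpp <- FstPresel:::cpp_pair_r2(pop@haps,
    rep(1L, 50L), as.integer(51:100))), 0.05)
})

test_that("allele-frequency trajectories are martingales under pure drift", {
  set.seed(12)
  # 100 near-independent loci (two per 50 cM on each of 50 chromosomes)
  map <- buildGenomeMap(genomeConfig(nChromosomes = 50L, nSnpsTotal = 100L,
                                     nQtl = 0L))
  pop <- simulateHistorical(map, historicalConfig(
    nGenerations = 25L, bottleneckGeneration = -1L, baseSize = 60L,
    finalSize = 60L))
  freq <- FstPresel:::alleleFreqs(pop, lociTable(pop)$locus)
  expect_equal(mean(freq), 0.5, tolerance = 0.07)
})

test_that("size schedule must cover every generation", {
  expect_error(historicalConfig(nGenerations = 10L, sizes = rep(50L, 5L)),
               "schedule")
  expect_error(historicalConfig(nGenerations = 5L,
                                sizes = c(50L, 50L, 1L, 50L, 50L, 50L)),
               ">= 2")
})

test_that("two-locus r2 under drift matches a brute-force Wright-Fisher
           simulator", {
  # two unlinked loci (different chromosomes), constant N = 30, 50
  # generations; compare the package simulator against the independent
  # minimal two-locus simulator via a two-sample z-test on mean r2
  sizes <- rep(30L, 51L)
  map <- buildGenomeMap(genomeConfig(nChromosomes = 2L, nSnpsTotal = 2L,
                                     nQtl = 0L))
  hist <- historicalConfig(nGenerations = 50L, bottleneckGeneration = -1L,
                           sizes = sizes)
  set.seed(21)
  pkg <- replicate(150, {
    pop <- suppressWarnings(tryCatch(simulateHistorical(map, hist),
                                     error = function(e) NULL))
    if (is.null(pop)) return(NA_real_)  # all loci fixed in this replicate
    f <- FstPresel:::alleleFreqs(pop, 1:2)
    if (any(f == 0 | f == 1)) NA_real_ else
      FstPresel:::cpp_pair_r2(pop@haps, 1L, 2L)
  })
  pkg <- pkg[!is.na(pkg)]
  set.seed(22)
  orc <- wfTwoLocusR2(sizes, cfrac = 0.5, nrep = 300)
  zse <- sqrt(var(pkg) / length(pkg) + var(orc) / length(orc))
  expect_lt(abs(mean(pkg) - mean(orc)), 4 * zse)
})

test_that("meiosis respects identical parents and tiny map lengths", {
  set.seed(31)
  map <- buildGenomeMap(genomeConfig(nChromosomes = 2L, nSnpsTotal = 100L,
                                     nQtl = 0L))
  pop <- simulateHistorical(map, historicalConfig(
    nGenerations = 0L, bottleneckGeneration = -1L, baseSize = 10L,
    finalSize = 10L))
  # identical parental haplotypes: crossing over is invisible
  pop2 <- pop
  pop2@haps[, 2L] <- pop2@haps[, 1L]
  g <- meiosis(pop2, 1L, n = 5L)
  expect_true(all(g == pop2@haps[, 1L]))

  # effectively zero map length: no crossovers, gamete is one whole
  # parental haplotype
  set.seed(32)
  mapTiny <- buildGenomeMap(genomeConfig(nChromosomes = 1L, nSnpsTotal = 50L,
                                         chromLengthCM = 1e-6, nQtl = 0L))
  popT <- simulateHistorical(mapTiny, historicalConfig(
    nGenerations = 0L, bottleneckGeneration = -1L, baseSize = 5L,
    finalSize = 5L))
  for (i in 1:20) {
    g <- meiosis(popT, 2L, n = 1L)
    expect_true(identical(as.vector(g), as.vector(popT@haps[, 3L])) ||
                  identical(as.vector(g), as.vector(popT@haps[, 4L])))
  }
})

test_that("recombination fraction over 50 cM matches the Haldane map
           function", {
  # 2 evenly spaced SNPs on a 100 cM chromosome sit 50 cM apart:
  # c = (1 - exp(-2 * 0.5)) / 2
  set.seed(33)
  map <- buildGenomeMap(genomeConfig(nChromosomes = 1L, nSnpsTotal = 2L,
                                     nQtl = 0L))
  haps <- matrix(as.raw(c(0L, 0L, 1L, 1L)), nrow = 2L)
  pop <- new("Population", haps = haps, map = map,
             pedigree = data.frame(id = 1L, sire = 0L, dam = 0L,
                                   generation = 0L, sex = NA_character_),
             tbv = NA_real_, phenotype = NA_real_, genotyped = FALSE,
             qtlEffects = numeric(0), ldSummary = list())
  g <- meiosis(pop, 1L, n = 1e5L)
  recFrac <- mean(g[1L, ] != g[2L, ])
  expect_equal(recFrac, (1 - exp(-1)) / 2, tolerance = 0.01)
})

test_that("offspring alleles are traceable to their parents", {
  set.seed(34)
  cfg <- presetConfig("micro")
  map <- buildGenomeMap(cfg$genome)
  pop <- simulateHistorical(map, cfg$hist)
  pop <- assignQtlEffects(pop)
  pop <- simulateSelectedPopulation(pop, cfg$sel)
  ped <- pedigree(pop)
  off <- which(ped$generation == 2L)[1:5]
  for (o in off) {
    pat <- pop@haps[, 2L * o - 1L]
    s <- ped$sire[o]
    ok <- pat == pop@haps[, 2L * s - 1L] | pat == pop@haps[, 2L * s]
    expect_true(all(ok))
    mat <- pop@haps[, 2L * o]
    d <- ped$dam[o]
    ok <- mat == pop@haps[, 2L * d - 1L] | mat == pop@haps[, 2L * d]
    expect_true(all(ok))
  }
  # pedigree is acyclic with parents in earlier generations
  expect_true(all(ped$generation[ped$sire[ped$sire > 0L]] <
                    ped$generation[ped$sire > 0L]))
})

test_that("seeded historical runs are bit-reproducible", {
  cfg <- genomeConfig(nChromosomes = 2L, nSnpsTotal = 40L, nQtl = 0L)
  h <- historicalConfig(nGenerations = 15L, bottleneckGeneration = 10L,
                        baseSize = 30L, bottleneckSize = 10L,
                        finalSize = 30L)
  run <- function() {
    set.seed(77)
    simulateHistorical(buildGenomeMap(cfg), h)@haps
  }
  expect_identical(run(), run())
})

test_that("marker panel selection keeps only segregating SNPs at the
           requested density", {
  set.seed(41)
  cfg <- genomeConfig(nChromosomes = 3L, nSnpsTotal = 30L, nQtl = 0L,
                      snpCandidateFactor = 6L)
  map <- buildGenomeMap(cfg)
  expect_equal(sum(lociTable(map)$type == "snp_cand"), 180L)
  pop <- simulateHistorical(map, historicalConfig(
    nGenerations = 40L, bottleneckGeneration = -1L, baseSize = 40L,
    finalSize = 40L))
  lc <- lociTable(pop)
  expect_equal(sum(lc$type == "snp"), 30L)
  expect_equal(as.vector(table(lc$chrom[lc$type == "snp"])), rep(10L, 3L))
  f <- FstPresel:::alleleFreqs(pop, snpLoci(pop))
  expect_true(all(f > 0 & f < 1))
  expect_equal(nrow(pop@haps), nrow(lc))
})
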