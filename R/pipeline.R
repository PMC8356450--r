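#' Experiment configuration presets
#'
#' Bundles genome, historical and selection configurations with the marker
#' preselection grid. Three scale presets are built in:
#' \describe{
#'   \item{full}{777 k SNPs on 30 chromosomes, 200 QTL on 2, historical
#'     sizes 4000 with a 600 bottleneck, 500 sires + 3500 dams, 3500 progeny
#'     over 7 generations, subsets 1-50 k. Full scale; cluster-sized.}
#'   \item{desk}{the same design with 9 k SNPs, historical sizes divided by
#'     10 (400 / 60), 50 sires + 350 dams, 350 progeny, subset sizes scaled
#'     by the full design's marker fractions (12, 116, 232, 347, 463, 579).}
#'   \item{micro}{a minimal layout (600 SNPs on 10 chromosomes, 40 QTL on 2,
#'     120 historical generations) for fast checks.}
#' }
#' Every field can be overridden through the list arguments.
#'
#' @param preset \code{"full"}, \code{"desk"}, \code{"micro"} or
#'   \code{"custom"} (equal to desk unless overridden).
#' @param genome,hist,sel named lists of overrides passed to
#'   [genomeConfig()], [historicalConfig()], [selectionConfig()].
#' @param subsetSizes preselection subset sizes (markers per criterion).
#' @param exclusionK number of unlinked markers removed in the exclusion
#'   panels.
#' @param tau blending weight for inverses.
#' @param fstFraction extreme-phenotype tail fraction.
#' @param qtlLayout \code{"two_chrom"} (QTL confined to 2 chromosomes) or
#'   \code{"all_chrom"} (spread over all chromosomes).
#' @return a list of class \code{experimentConfig}.
#' @export
presetConfig <- function(preset = c("desk", "full", "micro", "custom"),
                         genome = list(), hist = list(), sel = list(),
                         subsetSizes = NULL, exclusionK = NULL, tau = 0.05,
                         fstFraction = 0.05,
                         qtlLayout = c("two_chrom", "all_chrom")) {
  if (identical(preset, "paper")) preset <- "full"   # accepted alias
  preset <- match.arg(preset)
  qtlLayout <- match.arg(qtlLayout)
  base <- switch(preset,
    full = list(genome = list(), hist = list(), sel = list(),
                 subsetSizes = c(1, 10, 20, 30, 40, 50) * 1000L,
                 exclusionK = 50000L),
    desk = , custom = list(
      genome = list(nSnpsTotal = 9000L, snpCandidateFactor = 16L,
                    qtlCandidateFactor = 30L),
      hist = list(baseSize = 400L, bottleneckSize = 60L, finalSize = 400L),
      sel = list(progenyPerGeneration = 350L, nSires = 50L, nDams = 350L),
      subsetSizes = as.integer(round(c(1, 10, 20, 30, 40, 50) * 1000 /
                                       777000 * 9000)),
      exclusionK = as.integer(round(50000 / 777000 * 9000))),
    micro = list(
      genome = list(nChromosomes = 10L, nSnpsTotal = 600L, nQtl = 40L,
                    snpCandidateFactor = 4L),
      hist = list(nGenerations = 120L, bottleneckGeneration = 100L,
                  baseSize = 80L, bottleneckSize = 20L, finalSize = 80L),
      sel = list(nGenerations = 4L, progenyPerGeneration = 80L,
                 nSires = 10L, nDams = 70L),
      subsetSizes = c(2L, 8L, 16L, 23L, 31L, 39L),
      exclusionK = 39L))
  gcfg <- modifyList(base$genome, genome)
  if (qtlLayout == "all_chrom" && is.null(gcfg$qtlChromosomes)) {
    nc <- gcfg$nChromosomes %||% 30L
    gcfg$qtlChromosomes <- seq_len(nc)
  }
  structure(list(preset = preset, qtlLayout = qtlLayout,
                 genome = do.call(genomeConfig, gcfg),
                 hist = do.call(historicalConfig, modifyList(base$hist, hist)),
                 sel = do.call(selectionConfig, modifyList(base$sel, sel)),
                 subsetSizes = subsetSizes %||% base$subsetSizes,
                 exclusionK = exclusionK %||% base$exclusionK,
                 tau = tau, fstFraction = fstFraction),
            class = "experimentConfig")
}

# H inverse from precomputed parts (A and A22 inverses are shared across the
# marker-set grid of one replicate).
hinvFromParts <- function(Ainv, A22inv, Gstar, gidx) {
  H <- Ainv
  H[gidx, gidx] <- H[gidx, gidx] + pdInverse(Gstar, "G*") - A22inv
  H
}

# One replicate of the full workflow. Returns list(results, simSummary).
runReplicate <- function(config, seed, replicate = 1L,
                         includeRankingFits = TRUE, includeRandomFits = FALSE,
                         includeExclusion = TRUE, includePreselection = TRUE,
                         verbose = FALSE) {
  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  map <- buildGenomeMap(config$genome)
  pop <- simulateHistorical(map, config$hist)
  pop <- assignQtlEffects(pop, varG = config$sel$varG)
  pop <- simulateSelectedPopulation(pop, config$sel)
  tSim <- proc.time()[["elapsed"]] - t0

  ped <- pedigree(pop)
  lastGen <- config$sel$nGenerations
  training <- ped$generation >= 1L & ped$generation < lastGen
  gIdx <- which(pop@genotyped)
  gIds <- ped$id[gIdx]
  trainG <- ped$id[pop@genotyped & training]
  valIds <- ped$id[ped$generation == lastGen]
  tbv <- trueBV(pop)
  labels <- truthLabels(pop@map)
  snps <- snpLoci(pop)
  qtl <- qtlLoci(pop)

  geno <- dosageMatrix(pop, snps, gIdx)
  qtlGeno <- dosageMatrix(pop, qtl, gIdx)
  freqs <- alleleFreqs(pop, snps, gIdx)
  qfreqs <- alleleFreqs(pop, qtl, gIdx)

  A <- buildA(ped)
  Ainv <- pdInverse(A, "A")
  A22 <- subsetA22(A, gIds)
  A22inv <- pdInverse(A22, "A22")
  Gqtl <- buildGqtl(qtlGeno, freqs = qfreqs)

  pedFit <- solveABlup(pop@phenotype, ped, config$sel$varG, config$sel$varE)
  rows <- list()
  addRow <- function(name, criterion, size, acc, set = NULL, metrics = TRUE) {
    r <- data.frame(replicate = replicate, marker_set = name,
                    criterion = criterion, size = size, accuracy = acc,
                    n_markers = NA_real_, n_segregating = NA_real_,
                    overlap_pct = NA_real_, var_explained = NA_real_,
                    cor_noncentered = NA_real_, cor_centered = NA_real_,
                    positive_direction_fraction = NA_real_,
                    ms_error_median = NA_real_)
    if (!is.null(set)) {
      r$n_markers <- length(set)
      p <- freqs[as.character(set)]
      r$n_segregating <- sum(p > 0 & p < 1)
      r$overlap_pct <- overlapPct(set, labels)
      r$var_explained <- explained(set)
      if (metrics) {
        Gm <- buildG(geno, set, freqs)
        r$cor_noncentered <- matrixCorrelation(Gm, Gqtl, FALSE, ids = trainG)
        r$cor_centered <- matrixCorrelation(Gm, Gqtl, TRUE, A22, ids = trainG)
        dms <- directionalMS(Gm, Gqtl, A22, ids = trainG)
        r$positive_direction_fraction <- dms$positiveFraction
        mse <- msErrorPct(Gm, Gqtl, A22, ids = trainG)
        r$ms_error_median <- median(mse$values)
      }
    }
    rows[[length(rows) + 1L]] <<- r
  }

  # variance explained: tag QTL by max r2 with subset markers, among the
  # genotyped training individuals
  trIdx <- match(trainG, gIds)
  qtlTr <- qtlGeno[trIdx, , drop = FALSE]
  snpTr <- geno[trIdx, , drop = FALSE]
  pQ <- colMeans(qtlTr) / 2
  wQ <- 2 * pQ * (1 - pQ) * pop@qtlEffects[colnames(qtlTr)]^2
  segQ <- pQ > 0 & pQ < 1
  segS <- apply(snpTr, 2L, function(x) any(x != x[1L]))
  R2 <- matrix(0, ncol(qtlTr), ncol(snpTr),
               dimnames = list(colnames(qtlTr), colnames(snpTr)))
  if (any(segQ) && any(segS))
    R2[segQ, segS] <- suppressWarnings(
      cor(qtlTr[, segQ, drop = FALSE], snpTr[, segS, drop = FALSE]))^2
  explained <- function(set) {
    tagged <- segQ & apply(R2[, as.character(set), drop = FALSE], 1L,
                           max) > 0.9
    sum(wQ[tagged]) / sum(wQ[segQ])
  }

  fitSet <- function(set) {
    G <- buildG(geno, set, freqs)
    Hinv <- hinvFromParts(Ainv, A22inv, blendG(G, A22, config$tau),
                          match(gIds, ped$id))
    fit <- solveSsgblup(pop@phenotype, ped,
                        new("RelationshipMatrix", values = Hinv,
                            role = "H_inverse", ids = as.integer(ped$id),
                            alleleFreqs = numeric(0), markerSet = integer(0)),
                        config$sel$varG, config$sel$varE)
    fit
  }
  accOf <- function(fit) predictionAccuracy(fit, tbv, valIds)

  addRow("pedigree", "baseline", NA, accOf(pedFit))
  hq2 <- snps[labels == "HQ"]
  lq28 <- snps[labels == "LQ"]
  allFit <- fitSet(snps)
  addRow("all", "baseline", length(snps), accOf(allFit), snps)
  if (length(hq2)) addRow("hq2", "baseline", length(hq2),
                          accOf(fitSet(hq2)), hq2)
  if (length(lq28)) addRow("lq28", "baseline", length(lq28),
                           accOf(fitSet(lq28)), lq28)
  tBase <- proc.time()[["elapsed"]] - t0 - tSim

  conc <- list(corHQ = NA_real_, corLQ = NA_real_)
  if (includePreselection) {
  # preselection statistics
  phenTrainG <- phenotypes(pop)[as.character(trainG)]
  split <- splitExtremes(phenTrainG, config$fstFraction)
  fstTab <- fstScores(geno, split)
  fst <- setNames(fstTab$fst, fstTab$snp)
  aTrain <- allFit[match(trainG, allFit$id), ]
  effTab <- backsolveSnpEffects(aTrain, snpTr, freqs,
                                subsetA22(A, trainG), config$tau)
  absEff <- setNames(abs(effTab$effect), effTab$snp)
  conc <- scoreEffectConcordance(fst, absEff, labels,
                                 k = config$subsetSizes[2L])

  for (k in config$subsetSizes) {
    sF <- rankAndSelect(fst, k, pop@map)
    sE <- rankAndSelect(absEff, k, pop@map)
    sR <- randomSubset(snps, k)
    if (includeRankingFits) {
      addRow("fst", "fst", k, accOf(fitSet(sF)), sF)
      addRow("effect", "effect", k, accOf(fitSet(sE)), sE)
    } else {
      addRow("fst", "fst", k, NA_real_, sF)
      addRow("effect", "effect", k, NA_real_, sE)
    }
    addRow("random", "random", k,
           if (includeRandomFits) accOf(fitSet(sR)) else NA_real_, sR)
  }

  if (includeExclusion) {
    for (crit in c("fst", "effect")) {
      sc <- if (crit == "fst") fst else absEff
      for (end in c("top", "bottom")) {
        panel <- buildExclusionPanel(snps, labels, sc, config$exclusionK,
                                     end, pop@map)
        addRow(paste0("excl_", crit, "_", end), paste0("excl_", crit),
               length(panel), accOf(fitSet(panel)), panel, metrics = FALSE)
      }
    }
  }
  }
  tAll <- proc.time()[["elapsed"]] - t0

  sim <- data.frame(replicate = replicate, seed = seed,
                    mean_r2_snp = pop@ldSummary$meanR2Snp,
                    mean_r2_qtl = pop@ldSummary$meanR2Qtl,
                    mean_r2_snp_qtl = pop@ldSummary$meanR2SnpQtl,
                    fraction_segregating = pop@ldSummary$fractionSegregating,
                    founder_tbv_var = pop@ldSummary$founderTbvVar,
                    gen1_phen_var = pop@ldSummary$gen1PhenVar,
                    gen1_realized_h2 = pop@ldSummary$gen1RealizedH2,
                    cor_fst_effect_hq = conc$corHQ,
                    cor_fst_effect_lq = conc$corLQ,
                    time_simulation_s = tSim, time_baseline_fits_s = tBase,
                    time_total_s = tAll)
  if (verbose)
    message(sprintf("replicate %d: sim %.1fs, total %.1fs", replicate,
                    tSim, tAll))
  list(results = do.call(rbind, rows), simSummary = sim)
}

#' Run a replicated preselection experiment
#'
#' For each replicate: simulate the genome, LD history and selected
#' population; build pedigree and genomic relationship matrices; fit
#' single-step GBLUP for the baseline marker classes (all / truth-linked /
#' truth-unlinked), the F_ST-, effect- and randomly preselected subsets of
#' each configured size, and the unlinked-marker exclusion panels; back-solve
#' SNP effects from the all-marker fit; and evaluate validation accuracy,
#' truth-class overlap, genetic variance explained and the
#' Mendelian-sampling agreement metrics for every marker set.
#'
#' @param config an \code{experimentConfig} from [presetConfig()].
#' @param nReplicates number of replicates.
#' @param masterSeed master seed; replicate seeds are derived
#'   deterministically from it.
#' @param includeRankingFits fit ssGBLUP for the F_ST / effect subsets (the
#'   subsets and their composition metrics are always computed)?
#' @param includePreselection compute the preselection stage at all (extreme
#'   split, F_ST scores, back-solved effects, subsets, exclusion panels)?
#'   With \code{FALSE} only the baseline marker classes are evaluated.
#' @param includeRandomFits fit ssGBLUP for the random subsets?
#' @param includeExclusion build and fit the exclusion panels?
#' @param outDir optional directory for per-replicate checkpoints; completed
#'   replicates found there are loaded instead of recomputed.
#' @param verbose print per-replicate timing.
#' @return list of class \code{experimentResult} with \code{results} (one
#'   row per replicate x marker set), \code{simSummary} (one row per
#'   replicate), \code{aggregate}, and the \code{config}.
#' @export
runExperiment <- function(config, nReplicates = 1L, masterSeed = 1L,
                          includeRankingFits = TRUE,
                          includeRandomFits = FALSE, includeExclusion = TRUE,
                          includePreselection = TRUE, outDir = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(config, "experimentConfig"))
  seeds <- deriveSeeds(masterSeed, nReplicates)
  res <- list(); sims <- list()
  for (r in seq_len(nReplicates)) {
    cpR <- if (!is.null(outDir))
      file.path(outDir, sprintf("replicate_%03d_results.tsv", r))
    cpS <- if (!is.null(outDir))
      file.path(outDir, sprintf("replicate_%03d_sim.tsv", r))
    if (!is.null(outDir) && file.exists(cpR) && file.exists(cpS)) {
      res[[r]] <- read.table(cpR, header = TRUE, sep = "\t")
      sims[[r]] <- read.table(cpS, header = TRUE, sep = "\t")
      next
    }
    one <- runReplicate(config, seeds[r], r, includeRankingFits,
                        includeRandomFits, includeExclusion,
                        includePreselection, verbose)
    res[[r]] <- one$results
    sims[[r]] <- one$simSummary
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      write.table(one$results, cpR, sep = "\t", row.names = FALSE,
                  quote = FALSE)
      write.table(one$simSummary, cpS, sep = "\t", row.names = FALSE,
                  quote = FALSE)
    }
  }
  results <- do.call(rbind, res)
  structure(list(results = results, simSummary = do.call(rbind, sims),
                 aggregate = aggregateResults(results), config = config),
            class = "experimentResult")
}

#' Aggregate replicate results
#'
#' Mean, standard deviation and standard error of every metric per marker
#' set; single-replicate groups get NA dispersion.
#'
#' @param results the per-replicate result table of [runExperiment()].
#' @param groupKeys grouping columns.
#' @return aggregated data.frame.
#' @export
aggregateResults <- function(results,
                             groupKeys = c("marker_set", "criterion",
                                           "size")) {
  metrics <- setdiff(names(results), c(groupKeys, "replicate"))
  metrics <- metrics[vapply(results[metrics], is.numeric, logical(1))]
  key <- do.call(paste, c(lapply(results[groupKeys], function(x)
    ifelse(is.na(x), "<NA>", as.character(x))), sep = "\r"))
  out <- NULL
  for (k in unique(key)) {
    d <- results[key == k, ]
    row <- d[1L, groupKeys, drop = FALSE]
    row$n_replicates <- nrow(d)
    for (m in metrics) {
      v <- d[[m]][!is.na(d[[m]])]
      row[[paste0(m, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(m, "_sd")]] <- if (length(v) > 1L) sd(v) else NA_real_
      row[[paste0(m, "_se")]] <- if (length(v) > 1L)
        sd(v) / sqrt(length(v)) else NA_real_
    }
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' Write the report tables of an experiment
#'
#' Emits the per-replicate and aggregated tables plus the study-style
#' summary tables (accuracy, overlap and variance explained per criterion
#' and subset size; class and subset correlations with QTL relationships;
#' exclusion-panel accuracies). Under the all-chromosome QTL layout the
#' criterion-by-size accuracy / variance-explained summary is written as
#' \code{table8_allchrom.tsv}.
#'
#' @param exp an \code{experimentResult}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeReport <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    row.names = FALSE, quote = FALSE)
  wt(exp$results, "results_per_replicate.tsv")
  wt(exp$simSummary, "simulation_summary.tsv")
  wt(exp$aggregate, "results_aggregate.tsv")
  ag <- exp$aggregate
  grid <- ag[ag$criterion %in% c("random", "fst", "effect"), ]
  wide <- function(metric) {
    sizes <- sort(unique(grid$size))
    out <- data.frame(criterion = c("random", "fst", "effect"))
    for (s in sizes)
      out[[paste0("k", s)]] <- vapply(out$criterion, function(cr) {
        v <- grid[grid$criterion == cr & grid$size == s,
                  paste0(metric, "_mean")]
        if (length(v)) v else NA_real_
      }, numeric(1))
    out
  }
  allChrom <- exp$config$qtlLayout == "all_chrom"
  if (allChrom) {
    t8 <- rbind(cbind(metric = "accuracy", wide("accuracy")),
                cbind(metric = "gv_explained", wide("var_explained")))
    wt(t8, "table8_allchrom.tsv")
  } else {
    wt(wide("accuracy"), "table1_accuracy.tsv")
    wt(wide("overlap_pct"), "table2_overlap.tsv")
    wt(wide("var_explained"), "table3_varexplained.tsv")
  }
  corTab <- function(sel) {
    d <- ag[sel, c("marker_set", "size", "cor_noncentered_mean",
                   "cor_centered_mean")]
    d$relative_decrease <- (d$cor_noncentered_mean - d$cor_centered_mean) /
      d$cor_noncentered_mean
    d
  }
  wt(corTab(ag$marker_set %in% c("all", "hq2", "lq28")),
     "table4_class_correlations.tsv")
  wt(corTab(ag$marker_set == "fst"), "table5_fst_correlations.tsv")
  wt(corTab(ag$marker_set == "effect"), "table6_effect_correlations.tsv")
  excl <- ag[grepl("^excl_", ag$marker_set), ]
  if (nrow(excl)) {
    none <- ag$accuracy_mean[ag$marker_set == "all"]
    t7 <- data.frame(criterion = c("effect", "fst"), none = none)
    for (end in c("top", "bottom"))
      t7[[end]] <- vapply(t7$criterion, function(cr) {
        v <- excl$accuracy_mean[excl$marker_set == paste0("excl_", cr, "_",
                                                          end)]
        if (length(v)) v else NA_real_
      }, numeric(1))
    wt(t7, "table7_exclusion.tsv")
  }
  invisible(dir)
}

#' Binned histogram table
#'
#' Counts per bin for a metric vector; backs the distribution figures of the
#' Mendelian-sampling diagnostics.
#'
#' @param values numeric vector (e.g. [directionalMS()] values).
#' @param breaks number of bins or break vector.
#' @return data.frame with \code{lower}, \code{upper}, \code{count}.
#' @export
histogramTable <- function(values, breaks = 50L) {
  h <- hist(values, breaks = breaks, plot = FALSE)
  data.frame(lower = h$breaks[-length(h$breaks)], upper = h$breaks[-1L],
             count = h$counts)
}
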