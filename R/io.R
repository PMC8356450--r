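# Text I/O: PLINK PED/MAP genotypes, pedigree/phenotype CSV, QTL truth CSV,
# marker map TSV, YAML configuration.

#' Write genotypes as PLINK PED/MAP
#'
#' Biallelic coding with alleles \code{"1"} (reference, allele code 0) and
#' \code{"2"}. The MAP file carries chromosome, locus id, position in cM and
#' an integer bp position derived from the cM position (1 cM = 10 kb).
#'
#' @param geno 0/1/2 dosage matrix, individuals x SNPs (ids as rownames,
#'   locus ids as colnames).
#' @param map a [GenomeMap-class] or [Population-class] covering the loci.
#' @param prefix output path prefix (writes \code{prefix.ped},
#'   \code{prefix.map}).
#' @param ped optional pedigree data.frame supplying parent ids and sex.
#' @param phen optional named phenotype vector (missing written as -9).
#' @return the prefix, invisibly.
#' @export
writePlink <- function(geno, map, prefix, ped = NULL, phen = NULL) {
  lc <- lociTable(map)
  lidx <- match(as.integer(colnames(geno)), lc$locus)
  if (anyNA(lidx)) stop("genotype columns missing from the map")
  mapDf <- data.frame(chrom = lc$chrom[lidx],
                      id = paste0("snp", lc$locus[lidx]),
                      cm = lc$posCM[lidx],
                      bp = as.integer(round(lc$posCM[lidx] * 1e4)))
  write.table(mapDf, paste0(prefix, ".map"), row.names = FALSE,
              col.names = FALSE, quote = FALSE, sep = "\t")
  ids <- rownames(geno)
  getPed <- function(col, default) {
    if (is.null(ped)) return(rep(default, length(ids)))
    v <- ped[[col]][match(as.integer(ids), ped$id)]
    ifelse(is.na(v), default, v)
  }
  sexCode <- getPed("sex", "0")
  sexCode <- ifelse(sexCode == "M", "1", ifelse(sexCode == "F", "2", "0"))
  phenCol <- if (is.null(phen)) rep(-9, length(ids)) else {
    v <- phen[ids]; ifelse(is.na(v), -9, v)
  }
  a1 <- ifelse(geno >= 1, "2", "1")
  a2 <- ifelse(geno == 2, "2", "1")
  gcols <- matrix("", nrow(geno), 2L * ncol(geno))
  gcols[, seq(1L, by = 2L, length.out = ncol(geno))] <- a1
  gcols[, seq(2L, by = 2L, length.out = ncol(geno))] <- a2
  out <- cbind("1", ids, getPed("sire", 0L), getPed("dam", 0L), sexCode,
               phenCol, gcols)
  write.table(out, paste0(prefix, ".ped"), row.names = FALSE,
              col.names = FALSE, quote = FALSE, sep = " ")
  invisible(prefix)
}

#' Read PLINK PED/MAP genotypes
#'
#' Counts the \code{"2"} allele; any other allele symbol than \code{"1"} /
#' \code{"2"} (including the \code{"0"} missing code) raises an error naming
#' the offending record. Round-trips [writePlink()] output losslessly.
#'
#' @param prefix path prefix of the \code{.ped} / \code{.map} pair.
#' @return list with \code{geno} (dosage matrix), \code{map} (data.frame
#'   chrom/id/cm/bp) and \code{fam} (family columns of the PED file).
#' @export
readPlink <- function(prefix) {
  mp <- read.table(paste0(prefix, ".map"),
                   col.names = c("chrom", "id", "cm", "bp"))
  lines <- readLines(paste0(prefix, ".ped"))
  m <- nrow(mp)
  fam <- NULL
  geno <- matrix(0, length(lines), m)
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) != 6L + 2L * m)
      stop("PED line ", i, ": expected ", 6L + 2L * m, " fields, found ",
           length(f))
    al <- f[-seq_len(6L)]
    bad <- !al %in% c("1", "2")
    if (any(bad))
      stop("PED line ", i, " (individual ", f[2L], "): invalid allele '",
           al[which(bad)[1L]], "' at SNP ", mp$id[ceiling(which(bad)[1L] / 2)])
    geno[i, ] <- (al[c(TRUE, FALSE)] == "2") + (al[c(FALSE, TRUE)] == "2")
    fam <- rbind(fam, f[seq_len(6L)])
  }
  fam <- as.data.frame(fam, stringsAsFactors = FALSE)
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "phen")
  dimnames(geno) <- list(fam$iid, sub("^snp", "", mp$id))
  list(geno = geno, map = mp, fam = fam)
}

#' Write / read the pedigree-phenotype table as CSV
#'
#' Columns: id, sire, dam, generation, sex, phenotype, genotyped, tbv.
#'
#' @param pop a [Population-class].
#' @param path file path.
#' @export
writePedigreeCsv <- function(pop, path) {
  df <- cbind(pop@pedigree, phenotype = pop@phenotype,
              genotyped = pop@genotyped, tbv = pop@tbv)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePedigreeCsv
#' @export
readPedigreeCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam", "generation")
  if (!all(need %in% names(df)))
    stop("pedigree CSV must have columns ", paste(need, collapse = ", "))
  df
}

#' Write QTL truth (chromosome, position, effect) as CSV
#'
#' @param pop a [Population-class] with QTL effects assigned.
#' @param path file path.
#' @export
writeQtlTruth <- function(pop, path) {
  lc <- lociTable(pop)
  q <- lc[match(as.integer(names(pop@qtlEffects)), lc$locus), ]
  write.csv(data.frame(chrom = q$chrom, pos_cM = q$posCM,
                       effect = as.numeric(pop@qtlEffects)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the marker map with truth class column as TSV
#'
#' @param map a [GenomeMap-class] or [Population-class].
#' @param path file path.
#' @export
writeMarkerMap <- function(map, path) {
  lc <- lociTable(map)
  write.table(lc[lc$type == "snp", c("locus", "chrom", "posCM", "class")],
              path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Write / read an experiment configuration as YAML
#'
#' The file stores the preset name plus any overrides; [readConfig()]
#' resolves it back through [presetConfig()].
#'
#' @param config an \code{experimentConfig} from [presetConfig()].
#' @param path file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(presetConfig, c(list(preset = raw$preset %||% "custom"),
                          raw[setdiff(names(raw), "preset")]))
}
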