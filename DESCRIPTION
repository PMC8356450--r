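Package: FstPresel
Title: Marker Preselection by F_ST and Estimated Effects for Genomic Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of a breeding population under
    pedigree-BLUP selection, construction of pedigree (A), genomic (VanRaden G)
    and combined single-step (H) relationship matrices, single-step GBLUP
    prediction, and preselection of SNP marker subsets by Nei F_ST scores
    computed between extreme-phenotype subpopulations or by back-solved
    absolute SNP effects. Includes Mendelian-sampling agreement diagnostics
    between marker- and QTL-based genomic relationships, experiment
    orchestration over replicates and marker-set grids, and PLINK PED/MAP
    text input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, graphics, Rcpp, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
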