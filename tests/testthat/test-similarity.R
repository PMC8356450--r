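# Mendelian-sampling agreement diagnostics.

symMat <- function(v, n, ids = seq_len(n)) {
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  M[lower.tri(M)] <- v
  M <- M + t(M)
  diag(M) <- 1
  M
}

test_that("matrix correlation equals a flatten-and-correlate oracle", {
  set.seed(101)
  v1 <- rnorm(6); v2 <- 0.5 * v1 + rnorm(6, sd = 0.3); v3 <- rnorm(6)
  GM <- symMat(v1, 4); GQ <- symMat(v2, 4); A22 <- symMat(v3, 4)
  expect_equal(matrixCorrelation(GM, GQ), cor(v1, v2))
  expect_equal(matrixCorrelation(GM, GQ, centered = TRUE, A22 = A22),
               cor(v1 - v3, v2 - v3))
  # identical matrices correlate perfectly, centered or not
  expect_equal(matrixCorrelation(GM, GM), 1)
  expect_equal(matrixCorrelation(GM, GM, centered = TRUE, A22 = A22), 1)
  # constant matrix: undefined
  expect_warning(r <- matrixCorrelation(symMat(rep(0.2, 6), 4), GQ),
                 "constant")
  expect_true(is.na(r))
})

test_that("directional MS reproduces the hand-evaluated cases", {
  # pair deviations dm = gm - a22 of +-0.1; sd is taken over the pair set
  a22 <- symMat(rep(0, 6), 4)
  dm <- c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1)
  gm <- symMat(dm, 4)
  d <- directionalMS(gm, gm, a22)
  expect_equal(abs(d$values), abs(dm) / sd(dm), tolerance = 1e-9)
  expect_equal(d$positiveFraction, 1)
  # dm = +0.1 vs dq = -0.05 on every pair: the hand case |dm|/sd with a
  # negative sign
  gqOpp <- symMat(-dm / 2, 4)
  d2 <- directionalMS(gm, gqOpp, a22)
  expect_equal(d2$values, -abs(dm) / sd(dm), tolerance = 1e-9)
  expect_equal(d2$positiveFraction, 0)
  # marker deviation of zero scores zero
  gmMix <- symMat(c(0, 0.1, -0.1, 0.1, -0.1, 0.2), 4)
  d3 <- directionalMS(gmMix, gm, a22)
  expect_equal(d3$values[1], 0)
})

test_that("directional MS magnitudes are scale invariant", {
  set.seed(102)
  # pedigree-centered view: scaling the deviations (and recomputing sd)
  # leaves the standardized values unchanged
  v <- rnorm(10); q <- rnorm(10)
  A22 <- symMat(rep(0, 10), 5)
  d1 <- directionalMS(symMat(v, 5), symMat(q, 5), A22)
  d2 <- directionalMS(symMat(3 * v, 5), symMat(q, 5), A22)
  expect_equal(d2$values, d1$values, tolerance = 1e-9)
})

test_that("near-zero QTL deviations take the positive sign", {
  a22 <- symMat(rep(0, 6), 4)
  gm <- symMat(c(-0.1, 0.1, -0.1, 0.1, -0.1, 0.1), 4)
  gq <- symMat(c(0, 0.05, -0.05, 0.05, -0.05, 0.05), 4)
  d <- directionalMS(gm, gq, a22)
  expect_equal(d$nNearZero, 1L)
  expect_gt(d$values[1], 0 - 1e-12)
})

test_that("MS error reproduces the hand-evaluated cases", {
  a22 <- symMat(rep(0, 6), 4)
  gm <- symMat(c(0.2, -0.2, 0.2, -0.2, 0.2, -0.2), 4)   # sd = 0.2
  gq <- symMat(c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1), 4)   # sd = 0.1
  # standardized marker and QTL MS coincide -> 0%
  e <- msErrorPct(gm, gq, a22)
  expect_equal(e$values, rep(0, 6), tolerance = 1e-9)
  # a pair with gm = a22 exactly scores 100% (numerator reduces to the QTL
  # deviation itself)
  gmFlat <- symMat(c(0, 0.2, -0.2, 0.2, -0.2, 0.2), 4)
  e2 <- msErrorPct(gmFlat, gq, a22)
  expect_equal(e2$values[1], 100, tolerance = 1e-9)
  # dm = 0.2, dq = 0.1, both sds equal -> |(2 - 1)/1| = 100%
  gmBig <- symMat(c(0.2, -0.1, 0.1, -0.1, 0.1, -0.1), 4)
  sdM <- sd(c(0.2, -0.1, 0.1, -0.1, 0.1, -0.1))
  sdQ <- sd(c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1))
  e3 <- msErrorPct(gmBig, gq, a22)
  expect_equal(e3$values[1],
               100 * abs(0.2 / sdM - 0.1 / sdQ) / (0.1 / sdQ),
               tolerance = 1e-9)
})

test_that("MS error below 100 means the marker beats the pedigree
           expectation", {
  set.seed(103)
  GM <- symMat(rnorm(10), 5); GQ <- symMat(rnorm(10), 5)
  A22 <- symMat(rnorm(10, sd = 0.2), 5)
  e <- msErrorPct(GM, GQ, A22)
  pr <- FstPresel:::msPairs(GM, GQ, A22)
  m <- (pr$gm - pr$a) / sd(pr$gm)
  q <- (pr$gq - pr$a) / sd(pr$gq)
  below <- e$values < 100
  # distance of standardized marker MS to QTL MS vs distance of A22 (=0)
  expect_equal(below, abs(m - q) < abs(q))
})

test_that("overlap percentage counts truth-linked subset members", {
  labels <- setNames(rep(c("HQ", "LQ"), c(10, 90)), 1:100)
  expect_equal(overlapPct(1:10, labels), 100)
  expect_equal(overlapPct(11:30, labels), 0)
  expect_equal(overlapPct(6:15, labels), 50)
  expect_error(overlapPct(integer(0), labels), "empty")
})

test_that("variance explained responds to LD between subset and QTL", {
  set.seed(104)
  n <- 200L
  qtlG <- sapply(runif(5, 0.2, 0.8), function(p) rbinom(n, 2, p))
  dimnames(qtlG) <- list(1:n, 101:105)
  eff <- setNames(rnorm(5), 101:105)
  # markers in perfect LD with every QTL: copies of the QTL dosages
  snpG <- qtlG
  colnames(snpG) <- 1:5
  v <- varianceExplained(1:5, qtlG, snpG, eff)
  expect_equal(v$explainedFraction, 1)
  expect_true(all(v$perQtl))
  # independent markers: nothing tagged
  snpI <- sapply(runif(5, 0.2, 0.8), function(p) rbinom(n, 2, p))
  dimnames(snpI) <- list(1:n, 1:5)
  v0 <- varianceExplained(1:5, qtlG, snpI, eff)
  expect_equal(v0$explainedFraction, 0)
  # monomorphic QTL are excluded with a warning
  qtlG2 <- cbind(qtlG, `106` = rep(0, n))
  expect_warning(v2 <- varianceExplained(1:5, qtlG2, snpG,
                                         c(eff, `106` = 1)), "monomorphic")
  expect_equal(v2$nMonomorphic, 1L)
  expect_equal(v2$explainedFraction, 1)
})

test_that("score-effect concordance is 1 for monotone transforms and ~0 for
           shuffles", {
  set.seed(105)
  fst <- setNames(runif(400), 1:400)
  labels <- setNames(rep(c("HQ", "LQ"), 200), 1:400)
  mono <- scoreEffectConcordance(fst, fst^2 + fst, labels)  # not linear but
  expect_gt(mono$corHQ, 0.97)                               # near-perfect
  expect_gt(mono$corLQ, 0.97)
  shuf <- scoreEffectConcordance(fst, setNames(sample(fst), 1:400), labels)
  expect_lt(abs(shuf$corHQ), 0.2)
  expect_lt(abs(shuf$corLQ), 0.2)
  expect_equal(nrow(mono$table), 400L)
  # thresholds bound the top-k sets
  thr <- scoreEffectConcordance(fst, fst, labels, k = 10L)$thresholds
  expect_equal(sum(fst >= thr$fst), 10L)
})
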