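# BLUP solvers, SNP-effect back-solving, accuracy.

test_that("pedigree BLUP matches the closed form for unrelated individuals", {
  set.seed(71)
  n <- 12L
  ped <- data.frame(id = 1:n, sire = 0L, dam = 0L)
  y <- rnorm(n, 5)
  lambda <- 1.5
  fit <- solveABlup(y, ped, varG = 0.4, varE = 0.6)
  expect_equal(fit$ebv, (y - mean(y)) / (1 + lambda), tolerance = 1e-9)
  expect_equal(attr(fit, "mu"), mean(y), tolerance = 1e-9)
})

test_that("degenerate phenotype configurations shrink EBVs to zero", {
  ped <- data.frame(id = 1:6, sire = 0L, dam = 0L)
  fit <- solveABlup(rep(3.2, 6), ped)
  expect_equal(fit$ebv, rep(0, 6), tolerance = 1e-10)
  # lambda -> infinity
  y <- rnorm(6)
  fit2 <- solveABlup(y, ped, varG = 1e-9, varE = 1)
  expect_lt(max(abs(fit2$ebv)), 1e-6)
  # no records at all
  expect_error(solveABlup(rep(NA_real_, 6), ped), "no phenotype")
})

test_that("solutions are invariant to phenotype mean shifts", {
  set.seed(72)
  ped <- data.frame(id = 1:10, sire = c(rep(0L, 4), 1L, 1L, 2L, 2L, 5L, 5L),
                    dam = c(rep(0L, 4), 3L, 3L, 4L, 4L, 6L, 6L))
  y <- c(rnorm(8), NA, NA)
  f1 <- solveABlup(y, ped)
  f2 <- solveABlup(y + 100, ped)
  expect_equal(f1$ebv, f2$ebv, tolerance = 1e-8)
})

test_that("unphenotyped individuals get parent-average propagated EBVs", {
  set.seed(73)
  ped <- data.frame(id = 1:7, sire = c(0L, 0L, 0L, 0L, 1L, 3L, 5L),
                    dam = c(0L, 0L, 0L, 0L, 2L, 4L, 6L))
  y <- c(rnorm(6), NA)                       # individual 7 has no record
  fit <- solveABlup(y, ped)
  expect_equal(fit$ebv[7], (fit$ebv[5] + fit$ebv[6]) / 2, tolerance = 1e-8)
})

test_that("ssGBLUP equals pedigree BLUP when nothing is genotyped", {
  set.seed(74)
  ped <- data.frame(id = 1:8, sire = c(0L, 0L, 1L, 1L, 3L, 3L, 5L, 5L),
                    dam = c(0L, 0L, 2L, 2L, 4L, 4L, 6L, 6L))
  y <- c(rnorm(6), NA, NA)
  A <- buildA(ped)
  Hinv <- buildHinv(A, relValues(A)[0, 0], genotypedIds = integer(0))
  expect_equal(solveSsgblup(y, ped, Hinv)$ebv, solveABlup(y, ped)$ebv,
               tolerance = 1e-9)
})

test_that("fully genotyped ssGBLUP equals a dense GBLUP oracle", {
  set.seed(75)
  n <- 50L
  ped <- data.frame(id = 1:n, sire = 0L, dam = 0L)
  g <- matrix(rbinom(n * 120, 2, 0.4), n, 120, dimnames = list(1:n, 1:120))
  A <- buildA(ped)
  Gs <- blendG(buildG(g), relValues(A), 0.05)
  y <- rnorm(n)
  fit <- solveSsgblup(y, ped, buildHinv(A, Gs))
  # independent dense oracle: assemble the mean+animal MME from scratch
  lambda <- 0.6 / 0.4
  Ginv <- solve(relValues(Gs))
  C <- rbind(c(n, rep(1, n)), cbind(1, diag(n) + lambda * Ginv))
  sol <- solve(C, c(sum(y), y))
  expect_equal(fit$ebv, unname(sol[-1]), tolerance = 1e-8)
  # noiseless limit: injecting TBV as phenotypes with tiny residual variance
  tbv <- drop(scale(rnorm(n)))
  fitT <- solveSsgblup(tbv, ped, buildHinv(A, Gs), varG = 1, varE = 1e-8)
  expect_gt(cor(fitT$ebv, tbv), 0.999)
})

test_that("back-solved SNP effects satisfy the projection identity", {
  set.seed(76)
  n <- 15L; m <- 30L
  g <- matrix(rbinom(n * m, 2, 0.5), n, m, dimnames = list(1:n, 1:m))
  f <- setNames(rep(0.4, m), 1:m)            # external frequencies: ZZ'
  a <- rnorm(n)                              # full rank without blending
  u <- backsolveSnpEffects(setNames(a, 1:n), g, freqs = f, tau = 0)
  Z <- sweep(g, 2, 2 * f, "-")
  expect_equal(unname(drop(Z %*% u$effect)), a, tolerance = 1e-8)
  # zero breeding values give zero effects
  u0 <- backsolveSnpEffects(setNames(rep(0, n), 1:n), g, freqs = f, tau = 0)
  expect_equal(u0$effect, rep(0, m))
})

test_that("SNP-BLUP / GBLUP equivalence holds on an unblended full-rank toy", {
  set.seed(77)
  n <- 20L; m <- 60L
  ped <- data.frame(id = 1:n, sire = 0L, dam = 0L)
  g <- matrix(rbinom(n * m, 2, 0.5), n, m, dimnames = list(1:n, 1:m))
  f <- setNames(rep(0.5, m), 1:m)
  G <- buildG(g, freqs = f)
  y <- rnorm(n)
  fit <- solveSsgblup(y, ped, buildHinv(buildA(ped), G))
  u <- backsolveSnpEffects(fit, g, freqs = f, tau = 0)
  Z <- sweep(g, 2, 2 * f, "-")
  expect_equal(unname(drop(Z %*% u$effect)), fit$ebv, tolerance = 1e-8)
})

test_that("duplicating a SNP column splits its effect symmetrically", {
  set.seed(78)
  n <- 12L; m <- 25L
  g <- matrix(rbinom(n * m, 2, 0.5), n, m, dimnames = list(1:n, 1:m))
  f <- setNames(rep(0.5, m), 1:m)
  a <- rnorm(n)
  u1 <- backsolveSnpEffects(setNames(a, 1:n), g, freqs = f, tau = 0)
  gd <- cbind(g, g[, 1, drop = FALSE])
  colnames(gd) <- c(1:m, m + 1L)
  fd <- setNames(c(f, 0.5), colnames(gd))
  u2 <- backsolveSnpEffects(setNames(a, 1:n), gd, freqs = fd, tau = 0)
  # the two copies carry identical effects
  expect_equal(u2$effect[1], u2$effect[m + 1L], tolerance = 1e-8)
  # Sherman-Morrison oracle for the duplicated system: the pair sums to
  # 2/(1+s) times the original effect, with s = z' (ZZ')^-1 z
  Z <- sweep(g, 2, 2 * f, "-")
  M <- tcrossprod(Z)
  s <- drop(t(Z[, 1]) %*% solve(M, Z[, 1]))
  expect_equal(u2$effect[1] + u2$effect[m + 1L],
               2 / (1 + s) * u1$effect[1], tolerance = 1e-8)
  # and the projection identity is preserved by the duplicated panel
  Zd <- sweep(gd, 2, 2 * fd, "-")
  expect_equal(unname(drop(Zd %*% u2$effect)), a, tolerance = 1e-8)
})

test_that("a singular unblended system asks for blending", {
  set.seed(79)
  n <- 10L; m <- 4L                          # rank-deficient ZZ'
  g <- matrix(rbinom(n * m, 2, 0.5), n, m, dimnames = list(1:n, 1:m))
  expect_error(backsolveSnpEffects(setNames(rnorm(n), 1:n), g, tau = 0),
               "singular")
})

test_that("prediction accuracy behaves as a Pearson correlation", {
  tbv <- setNames(rnorm(50), 1:50)
  expect_equal(predictionAccuracy(tbv, tbv, 1:50), 1)
  expect_equal(predictionAccuracy(-tbv, tbv, 1:50), -1)
  expect_error(predictionAccuracy(tbv[1:2], tbv, 1:2), "at least 3")
  expect_warning(acc <- predictionAccuracy(setNames(rep(1, 50), 1:50), tbv,
                                           1:50), "zero variance")
  expect_true(is.na(acc))
  # equal-variance independent noise attenuates accuracy to 1/sqrt(2)
  set.seed(80)
  t2 <- setNames(rnorm(20000), seq_len(20000))
  e2 <- t2 + rnorm(20000)
  expect_equal(predictionAccuracy(e2, t2, seq_len(20000)), 1 / sqrt(2),
               tolerance = 0.02)
})

test_that("conjugate gradient agrees with the dense solve", {
  set.seed(81)
  n <- 300L
  ped <- data.frame(id = 1:n, sire = 0L, dam = 0L)
  for (i in 31:n) {
    ped$sire[i] <- sample.int(30L, 1L)
    ped$dam[i] <- sample.int(30L, 1L) ; while (ped$dam[i] == ped$sire[i])
      ped$dam[i] <- sample.int(30L, 1L)
  }
  A <- relValues(buildA(ped))
  C <- 1.5 * solve(A)
  diag(C) <- diag(C) + 1
  C <- rbind(c(n, rep(1, n)), cbind(1, C))
  b <- c(0, rnorm(n))
  x <- cgSolve(C, b, tol = 1e-12)
  xd <- solve(C, b)
  expect_lt(sqrt(sum((x - xd)^2)) / sqrt(sum(xd^2)), 1e-8)
  # the MME solver uses CG above its dense limit and matches the dense path
  y <- rnorm(n)
  fDense <- solveABlup(y, ped)
  fCG <- solveABlup(y, ped, denseLimit = 10L)
  expect_equal(fCG$ebv, fDense$ebv, tolerance = 1e-7)
})
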