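test_that("zero replacement uses half the global minimum and re-closes", {
  m <- rbind(c(0, 0.4, 0.6), c(0.5, 0.4, 0.1))
  colnames(m) <- c("a", "b", "c"); rownames(m) <- c("s1", "s2")
  out <- replaceZeros(m)
  # min non-zero is 0.1 -> zero becomes 0.05, row closed by 1.05
  expect_equal(out[1, ], c(a = 0.05, b = 0.4, c = 0.6) / 1.05)
  expect_equal(unname(rowSums(out)), c(1, 1))
  # no zeros: unchanged up to closure
  m2 <- makeComposition(5, 3, seed = 8)
  expect_equal(replaceZeros(m2), m2, tolerance = 1e-12)
  m3 <- m; m3[1, ] <- 0
  expect_error(replaceZeros(m3), "all-zero.*s1")
})

test_that("a large enough penalty shrinks every off-diagonal to zero", {
  comp <- makeComposition(100, 6, seed = 3)
  S <- cov(log(comp))
  Pm <- diag(6) - matrix(1 / 6, 6, 6)
  PSP <- Pm %*% S %*% Pm
  lamBig <- 1.2 * max(abs(PSP[upper.tri(PSP)]))
  lc <- fitLatentCorrelation(comp, lambda = lamBig)
  expect_true(all(lc@rho[upper.tri(lc@rho)] == 0))
})

test_that("an unpenalised fit recovers a strong planted correlation", {
  R <- plantedCorr(5, cbind(1, 2), 0.8)
  comp <- makeComposition(2000, 5, R, seed = 17)
  lc <- fitLatentCorrelation(comp, lambda = 0)
  rho <- latentRho(lc)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  best <- ut[which.max(abs(rho[upper.tri(rho)])), ]
  expect_equal(unname(sort(best)), c(1, 2))
  expect_gt(rho[1, 2], 0)
  # the clr-correlation oracle agrees on which pair dominates
  oracle <- cor(coabnet:::clr(comp))
  oBest <- which(abs(oracle) == max(abs(oracle[upper.tri(oracle)])),
                 arr.ind = TRUE)
  expect_setequal(unique(as.vector(oBest)), c(1, 2))
  expect_equal(rho[1, 2], oracle[1, 2], tolerance = 0.15)
})

test_that("a duplicated taxon column yields a near-unit estimate", {
  comp <- makeComposition(300, 4, seed = 23)
  comp <- cbind(comp, dup = comp[, 4])
  comp <- comp / rowSums(comp)
  lc <- fitLatentCorrelation(comp, lambda = 0.01)
  expect_gt(latentRho(lc)["g04", "dup"], 0.95)
})

test_that("the estimate is always a valid correlation matrix", {
  for (seed in 1:3) {
    R <- plantedCorr(8, rbind(c(1, 2), c(3, 4)), c(0.7, -0.5))
    comp <- makeComposition(60, 8, R, seed = seed)
    lc <- fitLatentCorrelation(comp, lambda = 0.02)
    rho <- latentRho(lc)
    expect_equal(rho, t(rho))
    expect_equal(unname(diag(rho)), rep(1, 8))
    expect_true(all(abs(rho) <= 1 + 1e-12))
    expect_gt(min(eigen(rho, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
  }
})

test_that("support sparsity is monotone non-increasing in the penalty", {
  R <- plantedCorr(10, rbind(c(1, 2), c(3, 4), c(5, 6)),
                   c(0.7, 0.6, -0.6))
  comp <- makeComposition(150, 10, R, seed = 41)
  nonzeros <- vapply(c(0, 0.01, 0.03, 0.1, 0.3), function(lam) {
    rho <- latentRho(fitLatentCorrelation(comp, lambda = lam))
    sum(abs(rho[upper.tri(rho)]) > 1e-10)
  }, numeric(1))
  expect_true(all(diff(nonzeros) <= 0))
})

test_that("estimates are invariant to rescaling one sample's basis", {
  R <- plantedCorr(6, cbind(1, 2), 0.6)
  comp <- makeComposition(80, 6, R, seed = 13)
  basis <- comp
  basis[1, ] <- basis[1, ] * 37     # rescale one sample's basis ...
  scaled <- basis / rowSums(basis)  # ... and close
  a <- fitLatentCorrelation(comp, lambda = 0.05, tol = 1e-8)
  b <- fitLatentCorrelation(scaled, lambda = 0.05, tol = 1e-8)
  expect_equal(latentRho(a), latentRho(b), tolerance = 1e-10)
})

test_that("non-convergence is flagged, not silently returned", {
  comp <- makeComposition(50, 8, seed = 2)
  expect_warning(lc <- fitLatentCorrelation(comp, lambda = 0.01,
                                            maxIter = 2L),
                 "did not converge")
  expect_false(lc@converged)
})

test_that("cross-validation picks the heaviest penalty on pure noise", {
  grid <- c(0.02, 0.4)
  hits <- vapply(1:20, function(s) {
    comp <- makeComposition(100, 8, seed = 100 + s)
    selectLambda(comp, grid = grid, kFolds = 5, seed = s)
  }, numeric(1))
  expect_gte(mean(hits == 0.4), 0.8)
  comp <- makeComposition(60, 6, seed = 1)
  expect_identical(selectLambda(comp, grid = 0.07), 0.07)
  expect_equal(selectLambda(comp, grid = grid, seed = 5),
               selectLambda(comp, grid = grid, seed = 5))
  expect_error(selectLambda(comp[1:3, ], grid = grid, kFolds = 5),
               "fewer samples")
})

test_that("edge extraction emits one estimate per unordered pair", {
  R <- diag(3)
  comp <- makeComposition(30, 3, seed = 6)
  lc <- fitLatentCorrelation(comp, lambda = 0.01, group = "g", region = "r")
  edges <- edgesFromMatrix(lc)
  expect_equal(nrow(edges), 3)
  expect_false(any(edges$taxonA == edges$taxonB))
  expect_true(all(edges$n == 30))
  # p = 93 gives the full pair universe of the cohort analysis
  expect_equal(choose(93, 2), 4278)
  big <- matrix(0, 93, 93); diag(big) <- 1
  dimnames(big) <- list(sprintf("t%02d", 1:93), sprintf("t%02d", 1:93))
  lc93 <- new("LatentCorrelation", rho = big, lambda = 0.1, n = 10L,
              group = "", region = "", converged = TRUE,
              iterations = 1L)
  expect_equal(nrow(edgesFromMatrix(lc93)), 4278)
})
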