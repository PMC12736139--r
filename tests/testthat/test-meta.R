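test_that("Fisher-Z transform matches its closed form and inverts", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fisherZ(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisherZ(-0.3), -fisherZ(0.3))
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(inverseFisherZ(fisherZ(r)), r, tolerance = 1e-12)
  expect_error(fisherZ(1), "\\|r\\| < 1")
})

test_that("pooling identical regions gives the degenerate closed form", {
  out <- poolRandomEffects(c(0.3, 0.3, 0.3), c(50, 50, 50))
  expect_equal(out$TE, atanh(0.3), tolerance = 1e-6)
  expect_equal(out$TE, 0.30952, tolerance = 1e-5)
  expect_equal(out$Q, 0)
  expect_equal(out$tau2, 0)
  expect_equal(out$seTE, 1 / sqrt(141), tolerance = 1e-12)
  expect_error(poolRandomEffects(0.3, 50), "at least 2 regions")
  expect_error(poolRandomEffects(c(0.1, 0.2), c(3, 50)), "n >= 4")
})

test_that("pooling matches a direct scalar evaluation of the DL formulas", {
  # independent oracle: straight transcription of the moment estimator
  dlOracle <- function(r, n) {
    z <- 0.5 * log((1 + r) / (1 - r))
    v <- 1 / (n - 3)
    w <- 1 / v
    zf <- sum(w * z) / sum(w)
    Q <- sum(w * (z - zf)^2)
    C <- sum(w) - sum(w^2) / sum(w)
    t2 <- max(0, (Q - (length(r) - 1)) / C)
    ws <- 1 / (v + t2)
    c(TE = sum(ws * z) / sum(ws), seTE = sqrt(1 / sum(ws)), tau2 = t2)
  }
  o <- dlOracle(c(0.3, 0.5), c(50, 60))
  out <- poolRandomEffects(c(0.3, 0.5), c(50, 60))
  expect_equal(out$TE, unname(o["TE"]), tolerance = 1e-10)
  expect_equal(out$tau2, unname(o["tau2"]), tolerance = 1e-10)
  expect_equal(out$seTE, unname(o["seTE"]), tolerance = 1e-10)
  # k duplicated regions: TE stays at z, seTE shrinks as 1/sqrt(k(n-3))
  for (k in c(2, 5)) {
    out <- poolRandomEffects(rep(0.4, k), rep(40, k))
    expect_equal(out$TE, atanh(0.4), tolerance = 1e-10)
    expect_equal(out$seTE, 1 / sqrt(k * 37), tolerance = 1e-10)
  }
})

test_that("pooling agrees with metafor's DerSimonian-Laird fit", {
  skip_if_not_installed("metafor")
  set.seed(99)
  for (i in 1:5) {
    r <- runif(3, -0.6, 0.6)
    n <- sample(30:200, 3)
    out <- poolRandomEffects(r, n)
    fit <- metafor::rma(yi = atanh(r), vi = 1 / (n - 3), method = "DL")
    expect_equal(out$TE, as.numeric(fit$beta), tolerance = 1e-10)
    expect_equal(out$seTE, fit$se, tolerance = 1e-10)
    expect_equal(out$tau2, fit$tau2, tolerance = 1e-10)
  }
})

test_that("the pooled effect lies between the regional effects", {
  set.seed(7)
  for (i in 1:50) {
    r <- runif(sample(2:5, 1), -0.8, 0.8)
    n <- sample(10:500, length(r), replace = TRUE)
    out <- poolRandomEffects(r, n)
    z <- atanh(r)
    expect_gte(out$TE, min(z) - 1e-12)
    expect_lte(out$TE, max(z) + 1e-12)
    expect_gte(out$tau2, 0)
  }
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhFDR(0.2), 0.2)
  expect_equal(bhFDR(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bhFDR(c(0.1, 1.2)), "outside")
  # order-preserving monotone transform of the raw p-values
  set.seed(3)
  p <- runif(40)
  expect_true(all(diff(bhFDR(p)[order(p)]) >= -1e-15))
  expect_true(all(bhFDR(p) >= p))
})

test_that("the significant network reports edges, sign fraction, degree", {
  pooled <- data.frame(
    pair = c("A-B", "A-C", "A-D", "B-C"),
    taxonA = c("A", "A", "A", "B"), taxonB = c("B", "C", "D", "C"),
    TE = c(0.5, -0.2, 0.4, 0.1), seTE = 0.1, group = "g",
    p = c(1e-5, 1e-4, 1e-3, 0.9))
  pooled$fdr <- bhFDR(pooled$p)
  nw <- significantNetwork(pooled, cut = 0.05)
  expect_equal(nrow(nw$edges), 3)
  expect_equal(nw$positiveFraction, 2 / 3)
  expect_equal(nw$degree[["A"]], 3)   # one taxon on all three edges
  allNull <- transform(pooled, p = 1, fdr = 1)
  nwNull <- significantNetwork(allNull)
  expect_equal(nrow(nwNull$edges), 0)
  expect_true(is.na(nwNull$positiveFraction))
})

test_that("per-group pooling assembles and adjusts the edge universe", {
  R <- plantedCorr(6, cbind(1, 2), 0.7)
  regs <- lapply(1:3, function(s) {
    comp <- makeComposition(150, 6, R, seed = 60 + s)
    edgesFromMatrix(fitLatentCorrelation(comp, lambda = 0.02,
                                         group = "g",
                                         region = paste0("R", s)))
  })
  pooled <- poolEdges(regs, group = "g")
  expect_equal(nrow(pooled), choose(6, 2))
  expect_true(all(pooled$fdr >= pooled$p))
  expect_equal(pooled$pair[which.min(pooled$p)], "g01-g02")
  expect_error(poolEdges(regs[1]), "at least 2 regions")
})
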