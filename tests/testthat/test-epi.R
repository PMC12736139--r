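# build a table with controlled prevalence: candidate taxon present in
# half the samples, remaining taxa drawn independently
nullEpiTable <- function(n = 60, p = 6, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rgamma(n * p, 2, 1), n, p,
                dimnames = list(sprintf("s%03d", 1:n),
                                sprintf("g%02d", 1:p)))
    m[sample(n, n / 2), 1] <- 0          # candidate absent in half
    m / rowSums(m)
  })
}

test_that("the candidate window is closed at both boundaries", {
  m <- matrix(1, 20, 4,
              dimnames = list(sprintf("s%02d", 1:20), letters[1:4]))
  m[1:15, 2] <- 0    # prevalence 0.25 exactly
  m[1:4, 3] <- 0     # prevalence 0.80: excluded
  m[1:5, 4] <- 0     # prevalence 0.75 exactly
  m <- m / rowSums(m)
  expect_setequal(epiCandidates(m), c("b", "d"))
  allFull <- matrix(1, 10, 3, dimnames = list(NULL, letters[1:3]))
  expect_length(epiCandidates(allFull / 3), 0)
})

test_that("D1 reproduces the hand-computed Bray-Curtis distance", {
  # candidate g0 present in 6 samples; the remaining two taxa have
  # renormalised mean profiles (0.5, 0.5) vs (0.8, 0.2)
  pres <- cbind(g0 = 0.2, a = 0.4, b = 0.4)
  abs_ <- cbind(g0 = 0, a = 0.8, b = 0.2)
  m <- rbind(pres[rep(1, 6), ], abs_[rep(1, 6), ])
  rownames(m) <- sprintf("s%02d", 1:12)
  ind <- epiIndicators(m, "g0", knn = 3)
  expect_equal(unname(ind["D1"]), 0.3, tolerance = 1e-12)
  expect_true(ind["D2"] >= 0 && ind["D2"] <= 1)
  expect_true(ind["Qmod"] >= -0.5 && ind["Qmod"] <= 1)
  expect_error(epiIndicators(m[1:8, ], "g0", knn = 3),
               "fewer than 5")
  expect_error(epiIndicators(m, "nope"), "unknown taxon")
})

test_that("indicators stay inside their ranges on random data", {
  for (s in 1:5) {
    m <- nullEpiTable(seed = s)
    ind <- epiIndicators(m, "g01")
    expect_true(ind["D1"] >= 0 && ind["D1"] <= 1)
    expect_true(ind["D2"] >= 0 && ind["D2"] <= 1)
    expect_true(ind["Qmod"] >= -0.5 && ind["Qmod"] <= 1)
  }
})

test_that("the internal KS statistic matches ks.test", {
  withr::with_seed(8, {
    for (i in 1:10) {
      x <- rnorm(30); y <- rnorm(40, 0.3)
      expect_equal(coabnet:::ksStat(x, y),
                   unname(suppressWarnings(
                     stats::ks.test(x, y)$statistic)),
                   tolerance = 1e-12)
    }
    # with ties
    x <- sample(1:5, 30, TRUE); y <- sample(1:5, 25, TRUE)
    expect_equal(coabnet:::ksStat(x, y),
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
                 tolerance = 1e-12)
  })
})

test_that("the permutation null is seed-deterministic and central", {
  m <- nullEpiTable(seed = 3)
  a <- epiNull(m, "g01", B = 50, seed = 5)
  b <- epiNull(m, "g01", B = 50, seed = 5)
  expect_identical(a, b)
  expect_error(epiNull(m, "g01", B = 0), "B must be >= 1")
  # a null taxon's observed indicator sits inside its own null
  obs <- epiIndicators(m, "g01")
  expect_lt(obs["D1"], quantile(a$null[, "D1"], 0.99))
})

test_that("a planted keystone is flagged and a null taxon is not", {
  cfg <- simConfig(pTaxa = 10, nPerStratum = matrix(100, 2, 2),
                   regions = c("R1", "R2"), baseSparsity = 0,
                   depth = 400, muSd = 1.5)
  ds <- simulateDataset(cfg, seed = 7)
  prev <- prevalence(ds@experiment)
  cand <- names(prev)[prev >= 0.3 & prev <= 0.7]
  skip_if(length(cand) < 2, "need two mid-prevalence taxa in this draw")
  key <- cand[1]; nullTaxon <- cand[2]
  # shift mid-abundance taxa: boosting the already-dominant taxa mostly
  # cancels under renormalisation, boosting mid ones moves the profile
  ab <- sort(colMeans(relAbundance(ds@experiment)), decreasing = TRUE)
  targets <- setdiff(names(ab), cand)[3:5]
  planted <- plantKeystone(ds, key, setNames(rep(2, 3), targets))
  m <- relAbundance(planted@experiment)
  obs <- epiIndicators(m, key)
  nul <- epiNull(m, key, B = 100, seed = 2)
  expect_gt(obs["D1"], nul$quantiles[1])
  expect_gt(obs["D2"], nul$quantiles[2])
  obs0 <- epiIndicators(m, nullTaxon)
  nul0 <- epiNull(m, nullTaxon, B = 100, seed = 3)
  # the untouched taxon should not beat its null at both indicators
  expect_false(obs0["D1"] > nul0$quantiles[1] &&
               obs0["D2"] > nul0$quantiles[2])
})

test_that("the keystone driver returns one row per usable candidate", {
  m <- nullEpiTable(n = 40, p = 5, seed = 9)
  res <- epiKeystone(m, B = 50, seed = 1)
  expect_true(all(res$prevalence >= 0.25 & res$prevalence <= 0.75))
  expect_true(all(c("isKeystoneD1", "isKeystoneD2", "isKeystoneQ") %in%
                  colnames(res)))
  expect_true(all(res$D1 >= 0 & res$D1 <= 1))
})
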