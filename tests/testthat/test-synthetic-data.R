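test_that("every generated abundance row is a closed composition", {
  ds <- simulateDataset(smallStudyConfig(p = 10, nPer = 30, depth = 5000),
                        seed = 3)
  m <- relAbundance(ds@experiment)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  expect_true(all(m >= 0))
  sd <- sampleData(ds@experiment)
  expect_setequal(unique(sd$group), c("nonMetS", "MetS"))
  expect_setequal(unique(sd$region), c("R1", "R2", "R3"))
  expect_equal(nrow(sd), 2 * 3 * 30)
})

test_that("identical config and seed give byte-identical datasets", {
  cfg <- smallStudyConfig(p = 8, nPer = 20, nDiff = 2, depth = 2000)
  a <- simulateDataset(cfg, seed = 11)
  b <- simulateDataset(cfg, seed = 11)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- simulateDataset(cfg, seed = 12)
  expect_false(identical(relAbundance(a@experiment),
                         relAbundance(c@experiment)))
})

test_that("independent taxa give near-zero clr correlations at depth", {
  # p large enough that the intrinsic clr bias (about -1/(p-1)) is small
  cfg <- simConfig(pTaxa = 40, nPerStratum = matrix(2000, 2, 1),
                   regions = "R1", baseSparsity = 0, depth = 1e6,
                   muSd = 0.5)
  ds <- simulateDataset(cfg, seed = 5)
  sd <- sampleData(ds@experiment)
  m <- relAbundance(ds@experiment)[sd$group == "nonMetS", ]
  cc <- cor(coabnet:::clr(replaceZeros(m)))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
})

test_that("a planted pair dominates the clr correlation", {
  cfg <- simConfig(pTaxa = 5, nPerStratum = matrix(2000, 2, 1),
                   regions = "R1", baseSparsity = 0, depth = 1e5,
                   differentialEdges = data.frame(
                     taxonA = "Genus001", taxonB = "Genus002",
                     rhoA = 0.8, rhoB = 0.8))
  ds <- simulateDataset(cfg, seed = 9)
  m <- relAbundance(ds@experiment)
  cc <- cor(coabnet:::clr(replaceZeros(m)))
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  best <- ut[which.max(abs(cc[upper.tri(cc)])), ]
  expect_equal(sort(rownames(cc)[best]), c("Genus001", "Genus002"))
})

test_that("infeasible planted structure is rejected with the eigenvalue", {
  # a correlation triangle with rho(1,2)=rho(1,3)=0.9, rho(2,3)=-0.9 is
  # not PSD for any completion
  cfg <- simConfig(pTaxa = 3, nPerStratum = matrix(10, 2, 1),
                   regions = "R1", baseSparsity = 0,
                   differentialEdges = data.frame(
                     taxonA = c("Genus001", "Genus001", "Genus002"),
                     taxonB = c("Genus002", "Genus003", "Genus003"),
                     rhoA = c(0.9, 0.9, -0.9), rhoB = c(0, 0, 0)))
  expect_error(simulateDataset(cfg, seed = 1),
               "positive semidefinite.*eigenvalue")
  expect_error(simConfig(differentialEdges = data.frame(
    taxonA = "Genus001", taxonB = "Genus002", rhoA = 1.2, rhoB = 0)),
    "rho")
})

test_that("function profiles follow the planted generative model", {
  # centred latents so the interaction is not absorbed by linear terms
  cfg <- simConfig(pTaxa = 6, nPerStratum = matrix(300, 2, 1),
                   regions = "R1", baseSparsity = 0, depth = 1e5,
                   muSd = 0)
  ds <- simulateDataset(cfg, seed = 21)
  # noiseless additive feature: additive model is a perfect fit
  y <- simulateFunctionProfile(ds, "Genus001", "Genus002",
                               beta1 = 1, beta2 = 0, noiseSd = 0)
  z <- ds@truth@latentLog
  fit <- fitNestedModels(y, z[, "Genus001"], z[, "Genus002"])
  expect_equal(fit$var_ind, 1, tolerance = 1e-9)
  expect_lt(fit$extra_var, 0.005)
  # pure interaction: the interaction term carries the variance
  y2 <- simulateFunctionProfile(ds, "Genus001", "Genus002",
                                beta12 = 2, noiseSd = 0.1, seed = 4)
  fit2 <- fitNestedModels(y2, z[, "Genus001"], z[, "Genus002"])
  expect_gt(fit2$var_int - fit2$var_ind, 0.5)
  expect_true(all(y >= 0) && all(y2 >= 0))
  expect_error(simulateFunctionProfile(ds, "Genus001", "nosuch"),
               "nosuch")
})

test_that("keystone planting shifts targets only where the taxon is present", {
  cfg <- simConfig(pTaxa = 8, nPerStratum = matrix(100, 2, 2),
                   regions = c("R1", "R2"), baseSparsity = 0,
                   depth = 300, muSd = 2)
  ds <- simulateDataset(cfg, seed = 5)
  prev <- prevalence(ds@experiment)
  cand <- names(prev)[prev > 0.3 & prev < 0.7][1]
  skip_if(is.na(cand), "no mid-prevalence taxon in this draw")
  targets <- setdiff(taxonIds(ds@experiment), cand)[1:3]
  planted <- plantKeystone(ds, cand, setNames(rep(2, 3), targets))
  expect_s4_class(planted, "SyntheticDataset")
  expect_identical(planted@truth@keystoneTaxa, cand)
  pres <- relAbundance(ds@experiment)[, cand] > 0
  dz <- planted@truth@latentLog - ds@truth@latentLog
  expect_true(all(abs(dz[pres, targets] - 2) < 1e-12))
  expect_true(all(dz[!pres, ] == 0))
  expect_true(all(dz[, setdiff(colnames(dz), targets)] == 0))
  expect_error(plantKeystone(ds, cand, setNames(1, cand)),
               "candidate itself")
  # prevalence outside the window is refused
  full <- names(prev)[prev > 0.95][1]
  skip_if(is.na(full), "no high-prevalence taxon in this draw")
  other <- setdiff(taxonIds(ds@experiment), c(cand, full))[1]
  expect_error(
    plantKeystone(ds, full, setNames(1, other),
                  prevalenceWindow = c(0.25, 0.75)),
    "outside the configured window")
})
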