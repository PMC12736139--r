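refDecomp <- function() {
  read.delim(system.file("extdata", "mets_variance_decomposition.tsv",
                         package = "coabnet"))
}

test_that("extra variance equals the difference of nested R-squared", {
  ref <- refDecomp()
  expect_lte(max(abs((ref$var_int - ref$var_ind) - ref$extra_var)), 1e-8)
  # the worked-example share of total explained variance
  share <- decompositionShare(list(extra_var = 0.00882859,
                                   var_int = 0.04792689))
  expect_equal(round(100 * share, 1), 18.4)
  expect_equal(decompositionShare(list(extra_var = 0, var_int = 0.3)), 0)
  expect_equal(decompositionShare(list(extra_var = 0.3, var_int = 0.3)), 1)
  expect_true(is.na(decompositionShare(list(extra_var = 0, var_int = 0))))
})

test_that("nested fits honour R-squared ordering and scale invariance", {
  withr::with_seed(21, {
    n <- 300
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 0.4 * x1 - 0.2 * x2 + 0.3 * x1 * x2 + rnorm(n)
    fit <- fitNestedModels(y, x1, x2)
    expect_gte(fit$var_int, fit$var_ind)
    expect_gte(fit$extra_var, 0)
    expect_equal(fit$extra_var, fit$var_int - fit$var_ind,
                 tolerance = 1e-12)
    # rank-based preprocessing makes the fit scale/shift invariant
    fit2 <- fitNestedModels(5 + 100 * y, x1, x2)
    expect_equal(fit2$var_int, fit$var_int, tolerance = 1e-12)
    expect_equal(fit2$p_interaction, fit$p_interaction, tolerance = 1e-12)
  })
})

test_that("a noiseless linear feature gives R-squared of one", {
  withr::with_seed(22, {
    x1 <- rnorm(600); x2 <- rnorm(600)
    fit <- fitNestedModels(x1, x1, x2)    # y = 1 * x1 exactly
    expect_equal(fit$var_ind, 1, tolerance = 1e-9)
  })
})

test_that("a pure interaction is attributed to the interaction term", {
  withr::with_seed(23, {
    x1 <- rnorm(600); x2 <- rnorm(600)
    fit <- fitNestedModels(x1 * x2, x1, x2)
    expect_gt(fit$extra_var, 0.5)
    expect_lt(fit$p_interaction, 1e-10)
  })
  expect_error(fitNestedModels(rnorm(20), 1:20, 1:20), "identical")
  expect_error(fitNestedModels(rnorm(5), rnorm(5), rnorm(5)), "n > 10")
})

test_that("null features rarely reach even modest explained variance", {
  withr::with_seed(24, {
    ok <- vapply(1:20, function(i) {
      x1 <- rnorm(600); x2 <- rnorm(600); y <- rnorm(600)
      fitNestedModels(y, x1, x2)$var_int < 0.03
    }, logical(1))
    expect_gte(mean(ok), 0.9)
  })
})

test_that("batch decomposition recovers the generating pair", {
  hits <- vapply(1:10, function(s) {
    cfg <- simConfig(pTaxa = 8, nPerStratum = matrix(300, 2, 1),
                     regions = "R1", baseSparsity = 0, depth = 5e4,
                     functionEffects = data.frame(
                       functionId = "ECX", taxonA = "Genus001",
                       taxonB = "Genus002", beta1 = 0.2, beta2 = 0.2,
                       beta12 = 0.3, noiseSd = 0.7))
    ds <- simulateDataset(cfg, seed = 700 + s)
    pairs <- data.frame(
      taxonA = sprintf("Genus%03d", c(1, 3, 5, 7)),
      taxonB = sprintf("Genus%03d", c(2, 4, 6, 8)))
    res <- batchDecompose(pairs, ds@functions,
                          relAbundance(ds@experiment))
    res$pair[which.max(res$extra_var)] == "Genus001-Genus002"
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("batch decomposition separates FDR families and checks inputs", {
  withr::with_seed(30, {
    m <- makeComposition(100, 4, seed = 31)
    fm <- matrix(rnorm(300), 100,
                 dimnames = list(rownames(m), c("EC:1", "EC:2", "KO:1")))
    pairs <- data.frame(taxonA = c("g01", "g03"), taxonB = c("g02", "g04"))
    res <- batchDecompose(pairs, fm, m,
                          functionKinds = c("EC", "EC", "KO"))
    expect_equal(nrow(res), 6)    # 2 pairs x 3 functions
    koFdr <- res$fdr_ind[res$function_kind == "KO"]
    expect_equal(koFdr, bhFDR(res$p_ind[res$function_kind == "KO"]))
    expect_error(batchDecompose(data.frame(taxonA = "zz", taxonB = "g01"),
                                fm, m), "zz")
  })
})
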