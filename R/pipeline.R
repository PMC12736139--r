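# End-to-end orchestration: filter -> per-(group, region) latent
# correlation -> per-group meta-analysis -> differential edges ->
# covariate adjustment -> keystone screening -> abundance/function tests
# -> variance decomposition.  Every stage is a pure function of
# (inputs, config, seed); the manifest records enough to re-run any stage
# in isolation.

#' Pipeline configuration
#'
#' @param minPrevalence prevalence threshold for the taxon filter
#'   (inclusive; default 0.10).
#' @param fdrCut FDR threshold for significant edges (default 0.05).
#' @param i2Cut I-squared threshold for differential calls (default
#'   0.75).
#' @param heteroPCut Q-test p threshold for differential calls (default
#'   0.05).
#' @param epiWindow prevalence window of keystone candidates.
#' @param permutations permutation count of the keystone null.
#' @param lambda fixed penalty for the latent-correlation fit; `NULL`
#'   selects per network by cross-validation over `lambdaGrid`.
#' @param lambdaGrid candidate penalties for cross-validation.
#' @param kFolds cross-validation folds.
#' @param eligible differential-edge eligibility rule (see
#'   [differentialEdges()]).
#' @param knn neighbourhood size of the keystone modularity graph.
#' @param seed integer seed for every stochastic stage.
#' @return configuration list of class `coabnet_pipeline_config`.
#' @export
pipelineConfig <- function(minPrevalence = 0.10, fdrCut = 0.05,
                           i2Cut = 0.75, heteroPCut = 0.05,
                           epiWindow = c(0.25, 0.75),
                           permutations = 200L, lambda = 0.05,
                           lambdaGrid = c(0.01, 0.02, 0.05, 0.1, 0.2),
                           kFolds = 5L,
                           eligible = "union", knn = 10L, seed = 1L) {
  for (v in list(minPrevalence = minPrevalence, fdrCut = fdrCut,
                 i2Cut = i2Cut, heteroPCut = heteroPCut)) {
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("thresholds must lie in [0, 1]")
  }
  structure(list(minPrevalence = minPrevalence, fdrCut = fdrCut,
                 i2Cut = i2Cut, heteroPCut = heteroPCut,
                 epiWindow = epiWindow,
                 permutations = as.integer(permutations),
                 lambda = lambda, lambdaGrid = lambdaGrid,
                 kFolds = as.integer(kFolds), eligible = eligible,
                 knn = as.integer(knn), seed = as.integer(seed)),
            class = "coabnet_pipeline_config")
}

#' Run the full differential co-abundance analysis
#'
#' @param x a [CoabundanceExperiment-class] with `group` and `region`
#'   columns in its sample data, or a [SyntheticDataset-class].
#' @param config a [pipelineConfig()].
#' @param functionTable optional samples-by-features matrix; taken from
#'   the dataset when `x` is synthetic.
#' @param functionKinds optional family label per function column.
#' @param runKeystone,runFunctions switch the keystone / function stages
#'   off for network-only runs.
#' @param verbose log one structured line per stage.
#' @return list with elements `filtered` (the filtered experiment),
#'   `latent` (per-stratum [LatentCorrelation-class]s), `pooled` (per
#'   group), `networks` (per-group [significantNetwork()] summaries),
#'   `differential` (edge table), `calls` ([callDifferential()] result),
#'   `adjusted`, `keystone`, `abundanceTests`, `functionTests`,
#'   `varianceDecomposition`, and `manifest`.
#' @export
runPipeline <- function(x, config = pipelineConfig(),
                        functionTable = NULL, functionKinds = NULL,
                        runKeystone = TRUE, runFunctions = TRUE,
                        verbose = FALSE) {
  stopifnot(inherits(config, "coabnet_pipeline_config"))
  if (is(x, "SyntheticDataset")) {
    if (is.null(functionTable) && ncol(x@functions))
      functionTable <- x@functions
    x <- x@experiment
  }
  if (!is(x, "CoabundanceExperiment"))
    stop("x must be a CoabundanceExperiment or SyntheticDataset")
  sd <- sampleData(x)
  if (!all(c("group", "region") %in% colnames(sd)))
    stop("sample data must provide 'group' and 'region' columns")
  if (!is.null(functionTable) &&
      nrow(functionTable) != ncol(x))
    stop("function table and abundance table disagree on the sample set")
  groups <- unique(as.character(sd$group))
  if (length(groups) != 2L)
    stop("exactly two groups are required, found: ",
         paste(groups, collapse = ", "))
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  filtered <- stage("filter",
                    filterByPrevalence(x, config$minPrevalence))
  say("filter", "%d of %d taxa kept at prevalence >= %g",
      nrow(filtered), nrow(x), config$minPrevalence)

  sd <- sampleData(filtered)
  latent <- stage("network", {
    out <- list()
    for (g in groups) {
      regions <- unique(as.character(sd$region[sd$group == g]))
      for (r in regions) {
        sel <- sd$group == g & sd$region == r
        sub <- relAbundance(filtered)[sel, , drop = FALSE]
        sub <- replaceZeros(closeRows(sub))
        lam <- config$lambda
        if (is.null(lam))
          lam <- selectLambda(sub, grid = config$lambdaGrid,
                              kFolds = config$kFolds,
                              seed = config$seed)
        out[[paste(g, r, sep = ":")]] <-
          fitLatentCorrelation(sub, lambda = lam, group = g, region = r)
      }
    }
    out
  })
  say("network", "%d stratum networks fitted", length(latent))

  pooled <- stage("meta", {
    out <- list()
    for (g in groups) {
      strata <- latent[vapply(latent, function(l) l@group == g,
                              logical(1))]
      if (length(strata) < 2L)
        stop("group '", g, "' has fewer than 2 regions; ",
             "pooling is undefined")
      out[[g]] <- poolEdges(lapply(strata, edgesFromMatrix), group = g)
    }
    out
  })
  networks <- lapply(pooled, significantNetwork, cut = config$fdrCut)
  for (g in groups)
    say("meta", "group %s: %d of %d edges significant (FDR < %g), %.1f%% positive",
        g, nrow(networks[[g]]$edges), nrow(pooled[[g]]), config$fdrCut,
        100 * networks[[g]]$positiveFraction)

  differential <- stage("diff",
    differentialEdges(pooled[[groups[1]]], pooled[[groups[2]]],
                      fdrCut = config$fdrCut, i2Cut = config$i2Cut,
                      pCut = config$heteroPCut,
                      eligible = config$eligible))
  calls <- callDifferential(differential)
  say("diff", "%d of %d eligible edges differential, involving %d genera",
      nrow(calls$edges), nrow(differential), calls$nGenera)

  adjusted <- NULL
  if (nrow(calls$edges)) {
    adjusted <- stage("adjust",
                      adjustEdges(filtered, calls$edges))
    say("adjust", "%d of %d differential edges robust to covariates",
        sum(adjusted$robust), nrow(adjusted))
  }

  keystone <- NULL
  if (runKeystone) {
    keystone <- stage("keystone",
      epiKeystone(filtered, B = config$permutations,
                  seed = config$seed, knn = config$knn,
                  window = config$epiWindow))
    say("keystone", "%d candidates screened, %d flagged by D1",
        nrow(keystone), sum(keystone$isKeystoneD1))
  }

  abundanceTests <- NULL
  if (nrow(calls$edges)) {
    abundanceTests <- stage("abundance-diff", {
      covs <- sd[, intersect(metadataCovariates(), colnames(sd)),
                 drop = FALSE]
      testFeatureDifferences(
        relAbundance(filtered)[, calls$genera, drop = FALSE],
        group = sd$group,
        covariates = if (ncol(covs)) covs else NULL,
        kind = "genus", caseLevel = groups[2])
    })
    say("abundance-diff", "%d of %d genera differ at FDR < %g",
        sum(abundanceTests$fdr < config$fdrCut, na.rm = TRUE),
        nrow(abundanceTests), config$fdrCut)
  }

  functionTests <- NULL
  varDecomp <- NULL
  if (runFunctions && !is.null(functionTable) && ncol(functionTable)) {
    fk <- functionKinds %||% rep("function", ncol(functionTable))
    functionTests <- stage("abundance-diff", {
      covs <- sd[, intersect(metadataCovariates(), colnames(sd)),
                 drop = FALSE]
      out <- list()
      for (k in unique(fk)) {
        out[[k]] <- testFeatureDifferences(
          functionTable[, fk == k, drop = FALSE], group = sd$group,
          covariates = if (ncol(covs)) covs else NULL,
          kind = k, caseLevel = groups[2])
      }
      do.call(rbind, out)
    })
    if (nrow(calls$edges)) {
      varDecomp <- stage("varexp",
        batchDecompose(calls$edges, functionTable,
                       relAbundance(filtered), functionKinds = fk))
      say("varexp", "%d (pair, function) decompositions",
          nrow(varDecomp))
    }
  }

  manifest <- list(
    seed = config$seed,
    configHash = rlang::hash(unclass(config)),
    inputHash = rlang::hash(relAbundance(x)),
    stages = list(
      filter = c(taxaIn = nrow(x), taxaKept = nrow(filtered)),
      network = length(latent),
      meta = vapply(networks, function(nw) nrow(nw$edges), integer(1)),
      diff = c(eligible = nrow(differential),
               differential = nrow(calls$edges),
               genera = calls$nGenera)))

  list(filtered = filtered, latent = latent, pooled = pooled,
       networks = networks, differential = differential, calls = calls,
       adjusted = adjusted, keystone = keystone,
       abundanceTests = abundanceTests, functionTests = functionTests,
       varianceDecomposition = varDecomp, manifest = manifest)
}
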