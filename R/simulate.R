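# Seeded generator for compositional microbiome studies with known
# ground truth.
#
# Latent model: logistic-normal.  Per (group, region) stratum, latent
# log-basis abundances are drawn from a multivariate normal with the
# stratum's planted correlation matrix; exponentiation and closure give
# the composition; counts are drawn multinomially at a finite sequencing
# depth and re-closed.  Zeros therefore arise only through the sampling
# depth - there is no separate zero-inflation knob - which is the same
# mechanism prevalence filtering responds to in real data.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the cohort the pipeline was
#' designed around: two phenotype groups of roughly 221 vs 382
#' participants spread over three regions, 93 genera, and multinomial
#' sampling at 50,000 reads per sample.
#'
#' @param pTaxa number of taxa (ignored when `taxa` is given).
#' @param taxa character vector of taxon ids.
#' @param groups two group labels; the first is the reference
#'   (control-like) group.
#' @param regions region labels (>= 1; the pipeline needs >= 2).
#' @param nPerStratum groups-by-regions integer matrix of sample counts.
#' @param baseSparsity fraction of off-diagonal pairs given a shared
#'   (non-differential) base correlation.
#' @param baseRhoRange absolute-value range the base correlations are
#'   drawn from (sign random).
#' @param differentialEdges `data.frame` with columns `taxonA`, `taxonB`,
#'   `rhoA`, `rhoB`: pairs whose latent correlation differs between the
#'   groups (A = first group).
#' @param depth multinomial sampling depth (reads per sample).
#' @param latentSd standard deviation of the latent log-abundances.
#' @param muSd spread of per-taxon baseline log-means (heterogeneous
#'   means give realistic uneven compositions).
#' @param covariateEffects `data.frame` with columns `covariate`,
#'   `taxon`, `beta`: per-unit (standardised) latent log shift.
#' @param functionEffects `data.frame` with columns `functionId`,
#'   `taxonA`, `taxonB`, `beta1`, `beta2`, `beta12`, `noiseSd`:
#'   functional features generated from two genera and their product on
#'   the latent log scale.
#' @return a validated configuration list of class `coabnet_sim_config`.
#' @export
simConfig <- function(pTaxa = 93L,
                      taxa = sprintf("Genus%03d", seq_len(pTaxa)),
                      groups = c("nonMetS", "MetS"),
                      regions = c("R1", "R2", "R3"),
                      nPerStratum = rbind(c(128L, 127L, 127L),
                                          c(74L, 74L, 73L)),
                      baseSparsity = 0.02,
                      baseRhoRange = c(0.3, 0.6),
                      differentialEdges = NULL,
                      depth = 50000L,
                      latentSd = 1,
                      muSd = 1,
                      covariateEffects = NULL,
                      functionEffects = NULL) {
  if (length(groups) != 2L) stop("exactly two groups are required")
  if (!length(regions)) stop("at least one region is required")
  nPerStratum <- matrix(as.integer(nPerStratum), length(groups),
                        length(regions),
                        dimnames = list(groups, regions))
  if (any(nPerStratum < 4L))
    stop("every (group, region) stratum needs n >= 4")
  if (anyDuplicated(taxa)) stop("duplicate taxon ids")
  de <- differentialEdges
  if (is.null(de))
    de <- data.frame(taxonA = character(0), taxonB = character(0),
                     rhoA = numeric(0), rhoB = numeric(0))
  if (nrow(de)) {
    missT <- setdiff(unique(c(de$taxonA, de$taxonB)), taxa)
    if (length(missT))
      stop("differential-edge taxa not in the taxon set: ",
           paste(missT, collapse = ", "))
    if (any(abs(c(de$rhoA, de$rhoB)) >= 1))
      stop("planted |rho| must be < 1")
    if (any(de$taxonA == de$taxonB))
      stop("a differential edge cannot join a taxon to itself")
  }
  fe <- functionEffects
  if (is.null(fe))
    fe <- data.frame(functionId = character(0), taxonA = character(0),
                     taxonB = character(0), beta1 = numeric(0),
                     beta2 = numeric(0), beta12 = numeric(0),
                     noiseSd = numeric(0))
  if (nrow(fe)) {
    missT <- setdiff(unique(c(fe$taxonA, fe$taxonB)), taxa)
    if (length(missT))
      stop("function-effect taxa not in the taxon set: ",
           paste(missT, collapse = ", "))
    if (any(fe$taxonA == fe$taxonB))
      stop("a function effect needs two distinct taxa")
    if (any(fe$noiseSd < 0)) stop("noiseSd must be >= 0")
  }
  ce <- covariateEffects
  if (is.null(ce))
    ce <- data.frame(covariate = character(0), taxon = character(0),
                     beta = numeric(0))
  structure(list(taxa = taxa, groups = groups, regions = regions,
                 nPerStratum = nPerStratum, baseSparsity = baseSparsity,
                 baseRhoRange = baseRhoRange, differentialEdges = de,
                 depth = as.integer(depth), latentSd = latentSd,
                 muSd = muSd, covariateEffects = ce,
                 functionEffects = fe),
            class = "coabnet_sim_config")
}

# Assemble one group's latent correlation matrix: shared base edges plus
# the group's planted differential values.  Base entries are shrunk (and
# the diagonal jittered) until the matrix is PSD; if it stays non-PSD
# even with the base edges fully removed, the *planted* structure itself
# is infeasible and is rejected with the offending eigenvalue.
.buildCorrelation <- function(taxa, baseEdges, plantedA, plantedB,
                              group1) {
  p <- length(taxa)
  base <- matrix(0, p, p, dimnames = list(taxa, taxa))
  if (nrow(baseEdges))
    for (i in seq_len(nrow(baseEdges))) {
      base[baseEdges$taxonA[i], baseEdges$taxonB[i]] <-
        base[baseEdges$taxonB[i], baseEdges$taxonA[i]] <- baseEdges$rho[i]
    }
  planted <- matrix(NA_real_, p, p, dimnames = list(taxa, taxa))
  pl <- if (group1) plantedA else plantedB
  if (nrow(pl))
    for (i in seq_len(nrow(pl))) {
      planted[pl$taxonA[i], pl$taxonB[i]] <-
        planted[pl$taxonB[i], pl$taxonA[i]] <- pl$rho[i]
    }
  shrink <- 1
  for (tries in 1:60) {
    R <- base * shrink
    R[!is.na(planted)] <- planted[!is.na(planted)]
    diag(R) <- 1
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-8) return(R)
    if (min(ev) > -1e-6) {          # nearly PSD: diagonal jitter
      R2 <- R + diag(1e-6 + abs(min(ev)), p)
      d <- sqrt(diag(R2)); R2 <- R2 / (d %o% d); diag(R2) <- 1
      if (min(eigen(R2, symmetric = TRUE,
                    only.values = TRUE)$values) > 1e-10)
        return(R2)
    }
    shrink <- shrink * 0.9
  }
  # infeasible even without base edges
  R <- matrix(0, p, p, dimnames = list(taxa, taxa))
  R[!is.na(planted)] <- planted[!is.na(planted)]
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  stop(sprintf(paste0("requested correlation structure is not positive ",
                      "semidefinite (min eigenvalue %.4g)"), min(ev)))
}

# Table-1-like covariate frequencies; group 2 is the case-like group
.simCovariates <- function(n, isCase) {
  if (isCase) {
    age <- rnorm(n, 56.22, 11.53)
    sex <- rbinom(n, 1, 0.5973)
    smoking <- sample(0:3, n, TRUE, prob = c(0.5656, 0.1765, 0.0226,
                                             0.2353))
    alcohol <- sample(0:3, n, TRUE, prob = c(0.5837, 0.3258, 0.0226,
                                             0.0679))
    activity <- sample(0:2, n, TRUE, prob = c(0.2172, 0.3620, 0.4208))
    dietMean <- c(357.70, 476.64, 114.62, 117.73, 177.85, 39.98)
    dietSd <- c(210.50, 282.53, 153.02, 184.43, 157.82, 51.83)
  } else {
    age <- rnorm(n, 50.81, 13.30)
    sex <- rbinom(n, 1, 0.3743)
    smoking <- sample(0:3, n, TRUE, prob = c(0.7356, 0.0785, 0.0157,
                                             0.1702))
    alcohol <- sample(0:3, n, TRUE, prob = c(0.5995, 0.3482, 0.0262,
                                             0.0262))
    activity <- sample(0:2, n, TRUE, prob = c(0.1885, 0.2932, 0.5183))
    dietMean <- c(369.19, 466.31, 147.54, 110.92, 202.98, 43.17)
    dietSd <- c(248.59, 279.95, 207.15, 126.43, 227.93, 60.00)
  }
  diet <- vapply(1:6, function(j) {
    shape <- (dietMean[j] / dietSd[j])^2
    rgamma(n, shape = shape, rate = shape / dietMean[j])
  }, numeric(n))
  colnames(diet) <- c("grains", "vegetables", "fruits", "dairy",
                      "animal_products", "beans_nuts")
  data.frame(age = age, sex = sex, smoking = smoking, alcohol = alcohol,
             physical_activity = activity, diet)
}

#' Generate a synthetic study with known network structure
#'
#' Draws, for every (group, region) stratum, latent log-abundances from a
#' multivariate normal with that stratum's planted correlation matrix,
#' applies covariate-taxon shifts, exponentiates and closes to a
#' composition, samples multinomial counts at the configured depth, and
#' re-closes.  Covariates, functional features (via the configured
#' two-genus effects) and the full ground truth are bundled alongside.
#' Byte-identical output is guaranteed for identical (config, seed).
#'
#' @param config a [simConfig()] object.
#' @param seed integer seed.
#' @return a [SyntheticDataset-class].
#' @export
simulateDataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "coabnet_sim_config"))
  withSeed(seed, {
    taxa <- config$taxa
    p <- length(taxa)
    # shared sparse base graph (same in both groups)
    nPairs <- p * (p - 1) / 2
    nBase <- round(config$baseSparsity * nPairs)
    ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    de <- config$differentialEdges
    dePairs <- if (nrow(de)) pairName(de$taxonA, de$taxonB) else character(0)
    utPairs <- pairName(taxa[ut[, 1L]], taxa[ut[, 2L]])
    avail <- which(!(utPairs %in% dePairs))
    baseEdges <- if (nBase > 0 && length(avail)) {
      pick <- sample(avail, min(nBase, length(avail)))
      data.frame(taxonA = taxa[ut[pick, 1L]], taxonB = taxa[ut[pick, 2L]],
                 rho = runif(length(pick), config$baseRhoRange[1],
                             config$baseRhoRange[2]) *
                       sample(c(-1, 1), length(pick), TRUE))
    } else {
      data.frame(taxonA = character(0), taxonB = character(0),
                 rho = numeric(0))
    }
    plantedA <- if (nrow(de))
      data.frame(taxonA = de$taxonA, taxonB = de$taxonB, rho = de$rhoA) else de
    plantedB <- if (nrow(de))
      data.frame(taxonA = de$taxonA, taxonB = de$taxonB, rho = de$rhoB) else de
    Rg <- list(.buildCorrelation(taxa, baseEdges, plantedA, plantedB, TRUE),
               .buildCorrelation(taxa, baseEdges, plantedA, plantedB, FALSE))
    names(Rg) <- config$groups
    mu <- rnorm(p, 0, config$muSd)

    latentCorr <- list()
    abundParts <- list(); metaParts <- list(); latentParts <- list()
    sampleCounter <- 0L
    for (gi in seq_along(config$groups)) {
      for (ri in seq_along(config$regions)) {
        gname <- config$groups[gi]; rname <- config$regions[ri]
        n <- config$nPerStratum[gi, ri]
        cov <- .simCovariates(n, isCase = gi == 2L)
        Z <- MASS::mvrnorm(n, mu = mu,
                           Sigma = Rg[[gi]] * config$latentSd^2)
        if (n == 1L) Z <- matrix(Z, nrow = 1L)
        colnames(Z) <- taxa
        ce <- config$covariateEffects
        if (nrow(ce))
          for (k in seq_len(nrow(ce))) {
            v <- cov[[ce$covariate[k]]]
            vs <- if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
            Z[, ce$taxon[k]] <- Z[, ce$taxon[k]] + ce$beta[k] * vs
          }
        comp <- exp(Z)
        comp <- comp / rowSums(comp)
        counts <- t(vapply(seq_len(n), function(i)
          rmultinom(1L, config$depth, comp[i, ])[, 1L],
          integer(p)))
        rel <- counts / config$depth
        ids <- sprintf("S%05d", sampleCounter + seq_len(n))
        sampleCounter <- sampleCounter + n
        rownames(rel) <- ids; colnames(rel) <- taxa
        rownames(Z) <- ids
        cov <- data.frame(group = gname, region = rname, cov,
                          row.names = ids, stringsAsFactors = FALSE)
        key <- paste(gname, rname, sep = ":")
        latentCorr[[key]] <- Rg[[gi]]
        abundParts[[key]] <- rel
        metaParts[[key]] <- cov
        latentParts[[key]] <- Z
      }
    }
    abundance <- do.call(rbind, abundParts)
    metadata <- do.call(rbind, metaParts)
    latent <- do.call(rbind, latentParts)
    rownames(metadata) <- rownames(abundance)

    fe <- config$functionEffects
    functions <- matrix(numeric(0), nrow(abundance), 0,
                        dimnames = list(rownames(abundance), NULL))
    if (nrow(fe)) {
      cols <- vapply(seq_len(nrow(fe)), function(k)
        .functionProfile(latent, fe$taxonA[k], fe$taxonB[k], fe$beta1[k],
                         fe$beta2[k], fe$beta12[k], fe$noiseSd[k]),
        numeric(nrow(abundance)))
      colnames(cols) <- fe$functionId
      functions <- cols
    }
    truth <- new("GroundTruth", latentCorr = latentCorr,
                 latentLog = latent, differentialPairs = de,
                 functionEffects = fe, keystoneTaxa = character(0))
    cexp <- CoabundanceExperiment(abundance, sampleData = metadata,
                                  relative = TRUE)
    new("SyntheticDataset", experiment = cexp, functions = functions,
        truth = truth, seed = as.integer(seed), config = unclass(config))
  })
}

.functionProfile <- function(latent, taxonA, taxonB, beta1, beta2,
                             beta12, noiseSd) {
  for (tx in c(taxonA, taxonB))
    if (!tx %in% colnames(latent)) stop("unknown taxon id: ", tx)
  if (taxonA == taxonB) stop("the two taxa must be distinct")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  za <- latent[, taxonA]; zb <- latent[, taxonB]
  y <- beta1 * za + beta2 * zb + beta12 * za * zb
  if (noiseSd > 0) y <- y + rnorm(length(y), 0, noiseSd)
  y - min(y)                       # shift to non-negative
}

#' Simulate one functional-feature column from two genera
#'
#' `Y = beta1*z_a + beta2*z_b + beta12*z_a*z_b + Normal(0, noiseSd)`
#' computed on the latent (pre-closure) log-abundances of the dataset,
#' then shifted to be non-negative.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param taxonA,taxonB distinct taxon ids.
#' @param beta1,beta2,beta12 linear and interaction coefficients.
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param seed optional seed for the noise draw.
#' @return numeric vector over the dataset's samples.
#' @export
simulateFunctionProfile <- function(dataset, taxonA, taxonB, beta1 = 0,
                                    beta2 = 0, beta12 = 0, noiseSd = 0,
                                    seed = NULL) {
  stopifnot(is(dataset, "SyntheticDataset"))
  withSeed(seed,
           .functionProfile(dataset@truth@latentLog, taxonA, taxonB,
                            beta1, beta2, beta12, noiseSd))
}

#' Plant a keystone taxon into an existing synthetic dataset
#'
#' In every sample where `taxon` is present (realised abundance > 0), the
#' latent log-abundances of the taxa named by `shiftVector` are shifted
#' by the given amounts; composition and counts are then regenerated
#' (deterministically from the dataset's seed).  The candidate taxon
#' itself may not be shifted.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param taxon the keystone candidate.
#' @param shiftVector named numeric vector: latent log shifts applied to
#'   other taxa in samples where `taxon` is present.
#' @param prevalenceWindow acceptable prevalence range of the candidate
#'   (error outside it, since downstream screening would drop it).
#' @return a new [SyntheticDataset-class] with the effect planted.
#' @export
plantKeystone <- function(dataset, taxon, shiftVector,
                          prevalenceWindow = c(0.05, 0.95)) {
  stopifnot(is(dataset, "SyntheticDataset"))
  m <- relAbundance(dataset@experiment)
  if (!taxon %in% colnames(m)) stop("unknown taxon id: ", taxon)
  targets <- names(shiftVector)
  if (is.null(targets) || !length(targets))
    stop("shiftVector must be a named vector of target taxa")
  if (taxon %in% targets)
    stop("the keystone candidate itself cannot be a shift target")
  missT <- setdiff(targets, colnames(m))
  if (length(missT)) stop("unknown taxon id: ", paste(missT, collapse = ", "))
  present <- m[, taxon] > 0
  prev <- mean(present)
  if (prev < prevalenceWindow[1] || prev > prevalenceWindow[2])
    stop(sprintf(paste0("candidate prevalence %.3f is outside the ",
                        "configured window [%.2f, %.2f]"),
                 prev, prevalenceWindow[1], prevalenceWindow[2]))
  Z <- dataset@truth@latentLog
  Z[present, targets] <- sweep(Z[present, targets, drop = FALSE], 2L,
                               shiftVector[targets], "+")
  depth <- dataset@config$depth
  rel <- withSeed(dataset@seed + 7919L, {
    comp <- exp(Z)
    comp <- comp / rowSums(comp)
    counts <- t(vapply(seq_len(nrow(comp)), function(i)
      rmultinom(1L, depth, comp[i, ])[, 1L], integer(ncol(comp))))
    counts / depth
  })
  dimnames(rel) <- dimnames(m)
  truth <- dataset@truth
  truth@latentLog <- Z
  truth@keystoneTaxa <- union(truth@keystoneTaxa, taxon)
  new("SyntheticDataset",
      experiment = CoabundanceExperiment(
        rel, sampleData = sampleData(dataset@experiment), relative = TRUE),
      functions = dataset@functions, truth = truth,
      seed = dataset@seed, config = dataset@config)
}

#' Write all artifacts of a synthetic dataset to a directory
#'
#' Emits `abundance.tsv`, `metadata.tsv`, `functions.tsv` (when any
#' functional features exist) and `truth.json`, all round-trippable
#' through the package readers.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if missing).
#' @return named character vector of the paths written.
#' @export
writeDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  writeAbundance(dataset@experiment, paths["abundance"])
  writeSampleMetadata(sampleData(dataset@experiment), paths["metadata"])
  writeGroundTruth(dataset@truth, paths["truth"])
  if (ncol(dataset@functions)) {
    paths["functions"] <- file.path(dir, "functions.tsv")
    writeFunctionTable(dataset@functions, paths["functions"])
  }
  paths
}
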