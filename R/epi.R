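# Keystone-candidate screening from cross-sectional presence-absence
# structure (EPI: empirical presence-abundance interrelation).
#
# For each candidate taxon, samples are split by its presence (> 0); the
# remaining taxa are renormalised per sample and three indicators measure
# how strongly the split separates the community:
#   D1 - Bray-Curtis distance between the two partitions' mean profiles;
#   D2 - mean two-sample Kolmogorov-Smirnov statistic over remaining taxa;
#   Q  - Newman modularity of the presence bipartition on a k-nearest-
#        neighbour sample graph built from Bray-Curtis similarities.
# Significance is judged against a presence-label permutation null
# (prevalence preserved exactly); a taxon is flagged by an indicator when
# the observed value exceeds the null's 95th percentile.

#' Candidate taxa for keystone screening
#'
#' Taxa whose prevalence (fraction of samples with abundance > 0) lies in
#' the closed window `[window[1], window[2]]`; taxa at exactly a boundary
#' are included.  Presence is evaluated on the table as given, before any
#' pseudocount replacement.
#'
#' @param x a [CoabundanceExperiment-class] or samples-by-taxa matrix.
#' @param window length-2 numeric prevalence window, default
#'   `c(0.25, 0.75)`.
#' @return character vector of candidate taxon ids.
#' @export
epiCandidates <- function(x, window = c(0.25, 0.75)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  prev <- prevalence(x)
  names(prev)[prev >= window[1] & prev <= window[2]]
}

# shared per-taxon precomputation: presence vector, renormalised profiles
# of the remaining taxa, and the k-NN graph over samples
.epiSetup <- function(m, taxon, knn) {
  if (!taxon %in% colnames(m))
    stop("unknown taxon: ", taxon)
  present <- m[, taxon] > 0
  rest <- m[, setdiff(colnames(m), taxon), drop = FALSE]
  rs <- rowSums(rest)
  ok <- rs > 0
  rest <- rest[ok, , drop = FALSE] / rs[ok]
  present <- present[ok]
  d <- as.matrix(vegan::vegdist(rest, method = "bray"))
  n <- nrow(rest)
  k <- min(knn, n - 1L)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    adj[i, nb] <- 1 - d[i, nb]
  }
  adj <- pmax(adj, t(adj))          # mutualise the k-NN relation
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  list(present = present, rest = rest, graph = g, n = n)
}

.epiFromSplit <- function(setup, present) {
  rest <- setup$rest
  mA <- colMeans(rest[present, , drop = FALSE])
  mB <- colMeans(rest[!present, , drop = FALSE])
  D1 <- sum(abs(mA - mB)) / sum(mA + mB)
  D2 <- mean(vapply(seq_len(ncol(rest)), function(j)
    ksStat(rest[present, j], rest[!present, j]), numeric(1)))
  Qmod <- igraph::modularity(setup$graph, membership = present + 1L,
                             weights = igraph::E(setup$graph)$weight)
  c(D1 = D1, D2 = D2, Qmod = Qmod)
}

#' EPI indicators for one candidate taxon
#'
#' @param x a [CoabundanceExperiment-class] or samples-by-taxa matrix of
#'   relative abundances.
#' @param taxon candidate taxon id.
#' @param knn neighbourhood size of the sample graph behind the
#'   modularity indicator (default 10).
#' @param minSide minimum samples required on each side of the presence
#'   split (default 5); fewer raises an error.
#' @return named numeric vector `c(D1, D2, Qmod)`.
#' @export
epiIndicators <- function(x, taxon, knn = 10L, minSide = 5L) {
  m <- abundanceMatrix(x)
  setup <- .epiSetup(m, taxon, knn)
  if (sum(setup$present) < minSide || sum(!setup$present) < minSide)
    stop("taxon ", taxon, " leaves fewer than ", minSide,
         " samples on one side of the presence split")
  .epiFromSplit(setup, setup$present)
}

#' Permutation null for the EPI indicators of one taxon
#'
#' Permutes the presence labels uniformly (the taxon's prevalence is
#' preserved exactly), recomputes all three indicators per permutation,
#' and returns the requested upper quantile of each null distribution.
#'
#' @inheritParams epiIndicators
#' @param B number of permutations (>= 1; the calibration tests use
#'   hundreds).
#' @param seed integer making the permutation stream reproducible.
#' @param probs quantile of the null returned per indicator
#'   (default 0.95).
#' @return list with `quantiles` (named vector at `probs`) and `null`
#'   (B-by-3 matrix of permuted indicator values).
#' @export
epiNull <- function(x, taxon, B = 200L, seed = 1L, knn = 10L,
                    probs = 0.95) {
  if (B < 1L) stop("B must be >= 1")
  m <- abundanceMatrix(x)
  setup <- .epiSetup(m, taxon, knn)
  null <- withSeed(seed, {
    t(vapply(seq_len(B), function(b)
      .epiFromSplit(setup, sample(setup$present)),
      numeric(3)))
  })
  colnames(null) <- c("D1", "D2", "Qmod")
  list(quantiles = apply(null, 2L, quantile, probs = probs, names = FALSE),
       null = null)
}

#' Screen all candidate taxa for keystone behaviour
#'
#' Runs [epiIndicators()] and [epiNull()] for every taxon in the
#' prevalence window and flags a taxon by an indicator when its observed
#' value exceeds the indicator's null 95th percentile.  Taxa leaving
#' fewer than `minSide` samples on a side of their presence split are
#' skipped with a message.
#'
#' @inheritParams epiNull
#' @param window prevalence window, default `c(0.25, 0.75)`.
#' @return `data.frame`: `taxon`, `prevalence`, `D1`, `D2`, `Qmod`,
#'   `null95_D1`, `null95_D2`, `null95_Qmod`, `isKeystoneD1`,
#'   `isKeystoneD2`, `isKeystoneQ`.
#' @export
epiKeystone <- function(x, B = 200L, seed = 1L, knn = 10L,
                        window = c(0.25, 0.75), minSide = 5L) {
  m <- abundanceMatrix(x)
  cand <- epiCandidates(m, window)
  prev <- prevalence(m)
  rows <- list()
  for (i in seq_along(cand)) {
    taxon <- cand[i]
    obs <- tryCatch(epiIndicators(m, taxon, knn = knn, minSide = minSide),
                    error = function(e) NULL)
    if (is.null(obs)) {
      message("skipping ", taxon,
              ": too few samples on one side of the presence split")
      next
    }
    nul <- epiNull(m, taxon, B = B, seed = seed + i, knn = knn)
    q <- nul$quantiles
    rows[[taxon]] <- data.frame(
      taxon = taxon, prevalence = unname(prev[taxon]),
      D1 = obs["D1"], D2 = obs["D2"], Qmod = obs["Qmod"],
      null95_D1 = q[1], null95_D2 = q[2], null95_Qmod = q[3],
      isKeystoneD1 = obs["D1"] > q[1],
      isKeystoneD2 = obs["D2"] > q[2],
      isKeystoneQ = obs["Qmod"] > q[3],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(0), prevalence = numeric(0),
               D1 = numeric(0), D2 = numeric(0), Qmod = numeric(0),
               null95_D1 = numeric(0), null95_D2 = numeric(0),
               null95_Qmod = numeric(0), isKeystoneD1 = logical(0),
               isKeystoneD2 = logical(0), isKeystoneQ = logical(0))
  rownames(out) <- NULL
  out
}
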