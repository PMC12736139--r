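# Random-effects meta-analysis of network edges across regions.
#
# Each edge is observed once per region as a latent correlation r with
# sample size n.  Pooling happens on the Fisher-Z scale with
# se = 1/sqrt(n - 3); between-region variance is estimated by the
# DerSimonian-Laird method-of-moments formula.

#' Fisher's Z transform and its inverse
#'
#' `fisherZ(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilising
#' transform of a correlation coefficient; `inverseFisherZ` maps back.
#'
#' @param r correlation(s), strictly inside (-1, 1).
#' @param z Fisher-Z effect(s).
#' @return numeric vector.
#' @examples
#' fisherZ(0.5)             # 0.5493
#' inverseFisherZ(fisherZ(0.3))
#' @export
fisherZ <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisherZ requires |r| < 1")
  0.5 * log((1 + r) / (1 - r))
}

#' @rdname fisherZ
#' @export
inverseFisherZ <- function(z) tanh(z)

#' Pool per-region correlations for one edge (DerSimonian-Laird)
#'
#' Transforms each region's correlation to the Fisher-Z scale
#' (`se_i = 1/sqrt(n_i - 3)`), estimates the between-region variance
#' `tau2` by the DerSimonian-Laird moment formula from the fixed-effect
#' Cochran's Q, and pools with inverse-variance random-effects weights
#' `1 / (se_i^2 + tau2)`.  The pooled effect is tested against zero by a
#' two-sided Wald (normal) test.
#'
#' @param r numeric vector of per-region correlations (length >= 2).
#' @param n integer vector of per-region sample sizes (each >= 4).
#' @return one-row `data.frame`: `TE`, `seTE`, `tau2`, `Q`, `df`, `p_Q`,
#'   `I2_regions`, `z`, `p`, `k`.
#' @examples
#' poolRandomEffects(c(0.3, 0.3, 0.3), c(50, 50, 50))
#' @export
poolRandomEffects <- function(r, n) {
  k <- length(r)
  if (k < 2L) stop("pooling needs at least 2 regions, got ", k)
  if (length(n) != k) stop("r and n must have equal length")
  if (any(n < 4)) stop("each region needs n >= 4")
  z <- fisherZ(r)
  se2 <- 1 / (n - 3)
  w <- 1 / se2
  zFE <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zFE)^2)
  df <- k - 1L
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  wStar <- 1 / (se2 + tau2)
  TE <- sum(wStar * z) / sum(wStar)
  seTE <- 1 / sqrt(sum(wStar))
  zstat <- TE / seTE
  data.frame(
    TE = TE, seTE = seTE, tau2 = tau2, Q = Q, df = df,
    p_Q = pchisq(Q, df, lower.tail = FALSE),
    I2_regions = if (Q > 0) max(0, (Q - df) / Q) else 0,
    z = zstat, p = 2 * pnorm(-abs(zstat)), k = k)
}

#' Pool all edges of one group across regions
#'
#' Applies [poolRandomEffects()] to every unordered taxon pair present in
#' all supplied per-region edge tables, then adjusts the Wald p-values by
#' Benjamini-Hochberg across the full pair universe of the group.
#'
#' @param regionEdges list of per-region edge `data.frame`s from
#'   [edgesFromMatrix()] (columns `pair`, `taxonA`, `taxonB`, `r`, `n`);
#'   at least two elements.
#' @param group optional group label stored in the output.
#' @return `data.frame`, one row per pair: `pair`, `taxonA`, `taxonB`,
#'   `group`, `TE`, `seTE`, `tau2`, `Q`, `p_Q`, `z`, `p`, `fdr`.
#' @export
poolEdges <- function(regionEdges, group = "") {
  if (!is.list(regionEdges) || length(regionEdges) < 2L)
    stop("pooling needs edge tables from at least 2 regions")
  pairs <- regionEdges[[1L]]$pair
  for (e in regionEdges[-1L]) {
    if (!setequal(e$pair, pairs))
      stop("per-region edge tables disagree on the pair universe")
  }
  first <- regionEdges[[1L]]
  rMat <- vapply(regionEdges,
                 function(e) e$r[match(pairs, e$pair)], numeric(length(pairs)))
  nMat <- vapply(regionEdges,
                 function(e) e$n[match(pairs, e$pair)], numeric(length(pairs)))
  res <- lapply(seq_along(pairs), function(i)
    poolRandomEffects(rMat[i, ], nMat[i, ]))
  res <- do.call(rbind, res)
  out <- data.frame(
    pair = pairs,
    taxonA = first$taxonA,
    taxonB = first$taxonB,
    group = if (nzchar(group)) group else first$group[1L],
    res[, c("TE", "seTE", "tau2", "Q", "p_Q", "z", "p")],
    stringsAsFactors = FALSE)
  out$fdr <- bhFDR(out$p)
  rownames(out) <- NULL
  out
}

#' Extract the significant network of one group
#'
#' Edges with `fdr < cut`, together with the summaries used to describe
#' the group networks: the fraction of retained edges with positive
#' pooled effect, and the per-taxon degree distribution.
#'
#' @param pooled pooled-edge `data.frame` from [poolEdges()].
#' @param cut FDR threshold (default 0.05).
#' @return list with elements `edges` (the retained rows),
#'   `positiveFraction` (`NA` when no edge is retained), and `degree`
#'   (named integer vector over incident taxa).
#' @export
significantNetwork <- function(pooled, cut = 0.05) {
  edges <- pooled[!is.na(pooled$fdr) & pooled$fdr < cut, , drop = FALSE]
  posFrac <- if (nrow(edges)) mean(edges$TE > 0) else NA_real_
  degree <- if (nrow(edges)) {
    tab <- table(c(edges$taxonA, edges$taxonB))
    structure(as.integer(tab), names = names(tab))
  } else {
    structure(integer(0), names = character(0))
  }
  list(edges = edges, positiveFraction = posFrac, degree = degree)
}
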