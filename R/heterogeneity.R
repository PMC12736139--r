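# Between-group differential-edge calling.
#
# Each edge has one pooled Fisher-Z effect per group.  With two estimates
# the fixed-effect Cochran's Q has one degree of freedom, and an edge is
# called differential when I2 > 0.75 and the Q-test p < 0.05 jointly.

#' Cochran's Q heterogeneity between two pooled effects
#'
#' Given the pooled Fisher-Z effect and standard error of each group,
#' computes the inverse-variance weighted mean, the fixed-effect Q
#' statistic (df = 1), `I2 = max(0, (Q - 1)/Q)` and the chi-square tail
#' probability.  All arguments are vectorised over edges.
#'
#' @param teA,teB pooled Fisher-Z effects of the two groups.
#' @param seA,seB their standard errors (> 0).
#' @return `data.frame` with columns `Q`, `I2`, `hetero_p`.
#' @examples
#' betweenGroupHeterogeneity(-0.1516305, 0.06792643,
#'                           -0.4312161, 0.11578319)
#' @export
betweenGroupHeterogeneity <- function(teA, seA, teB, seB) {
  if (any(seA <= 0) || any(seB <= 0))
    stop("standard errors must be > 0")
  wA <- 1 / seA^2
  wB <- 1 / seB^2
  zbar <- (wA * teA + wB * teB) / (wA + wB)
  Q <- wA * (teA - zbar)^2 + wB * (teB - zbar)^2
  I2 <- ifelse(Q > 0, pmax(0, (Q - 1) / Q), 0)
  data.frame(Q = Q, I2 = I2,
             hetero_p = pchisq(Q, df = 1, lower.tail = FALSE))
}

#' Build the differential-edge table from two pooled group networks
#'
#' Joins the pooled-edge tables of the two groups on pair identity,
#' restricts to the eligible set (by default the union of edges with
#' `fdr < fdrCut` in either group), computes between-group heterogeneity
#' per edge, and flags differential edges (`I2 > i2Cut` and
#' `hetero_p < pCut`) and direction changes (`sign(TE_A) != sign(TE_B)`).
#' No multiplicity adjustment is applied to `hetero_p`: the criterion is
#' the pre-specified conjunction of the raw Q-test p and the I-squared
#' threshold.
#'
#' @param pooledA,pooledB pooled-edge `data.frame`s from [poolEdges()]
#'   for the two groups (same pair universe).
#' @param fdrCut per-group FDR threshold defining eligibility.
#' @param i2Cut I-squared threshold for a differential call.
#' @param pCut heterogeneity-p threshold for a differential call.
#' @param eligible which edges enter the heterogeneity test: `"union"`
#'   (significant in either group), `"intersection"`, or `"all"` pairs.
#' @return `data.frame`, one row per eligible edge: `pair`, `taxonA`,
#'   `taxonB`, `TE_A`, `TE_B`, `seTE_A`, `seTE_B`, `groupA`, `groupB`,
#'   `fdr_A`, `fdr_B`, `Q`, `I2`, `hetero_p`, `is_differential`,
#'   `direction_change`.
#' @export
differentialEdges <- function(pooledA, pooledB, fdrCut = 0.05,
                              i2Cut = 0.75, pCut = 0.05,
                              eligible = c("union", "intersection",
                                           "all")) {
  eligible <- match.arg(eligible)
  if (!setequal(pooledA$pair, pooledB$pair))
    stop("the two groups disagree on the pair universe")
  idx <- match(pooledA$pair, pooledB$pair)
  b <- pooledB[idx, , drop = FALSE]
  sigA <- !is.na(pooledA$fdr) & pooledA$fdr < fdrCut
  sigB <- !is.na(b$fdr) & b$fdr < fdrCut
  keep <- switch(eligible,
                 union = sigA | sigB,
                 intersection = sigA & sigB,
                 all = rep(TRUE, nrow(pooledA)))
  a <- pooledA[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  het <- if (nrow(a)) {
    betweenGroupHeterogeneity(a$TE, a$seTE, b$TE, b$seTE)
  } else {
    data.frame(Q = numeric(0), I2 = numeric(0), hetero_p = numeric(0))
  }
  out <- data.frame(
    pair = a$pair, taxonA = a$taxonA, taxonB = a$taxonB,
    TE_A = a$TE, TE_B = b$TE, seTE_A = a$seTE, seTE_B = b$seTE,
    groupA = if (nrow(a)) a$group else character(0),
    groupB = if (nrow(b)) b$group else character(0),
    fdr_A = a$fdr, fdr_B = b$fdr,
    het,
    stringsAsFactors = FALSE)
  out$is_differential <- out$I2 > i2Cut & out$hetero_p < pCut
  out$direction_change <- sign(out$TE_A) != sign(out$TE_B)
  rownames(out) <- NULL
  out
}

#' Subset the differential calls and summarise the genera involved
#'
#' @param edges `data.frame` from [differentialEdges()].
#' @return list with `edges` (rows flagged differential), `genera`
#'   (sorted distinct incident genus names), `nGenera`, and
#'   `directionChanges` (pairs whose pooled effects disagree in sign).
#' @export
callDifferential <- function(edges) {
  hit <- edges[edges$is_differential %in% TRUE, , drop = FALSE]
  genera <- sort(unique(c(hit$taxonA, hit$taxonB)))
  list(edges = hit,
       genera = genera,
       nGenera = length(genera),
       directionChanges = hit$pair[hit$direction_change])
}
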