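# Between-group abundance / function testing: rank-based inverse normal
# transform, covariate residualisation by OLS, Wilcoxon rank-sum on the
# residuals, BH correction within each feature family.

#' Rank-based inverse normal transformation
#'
#' Maps values through the standard-normal quantile of
#' `(rank - offset) / (n - 2*offset + 1)` with average ranks for ties;
#' the default `offset = 0.375` is the Blom convention.  The transform is
#' monotone in the input.
#'
#' @param values numeric vector (length >= 2, not all tied).
#' @param offset rank offset; 0.375 (Blom) by default.
#' @return numeric vector of normal scores.
#' @examples
#' inverseRankTransform(c(3, 1, 2))
#' @export
inverseRankTransform <- function(values, offset = 0.375) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (length(unique(values)) == 1L)
    stop("constant vector: the rank transform is degenerate")
  r <- rank(values, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Residualise values on covariates by ordinary least squares
#'
#' Regresses `values` on an intercept plus the numerically encoded
#' covariates and returns the residuals.  A rank-deficient design is an
#' error naming the collinear column(s).
#'
#' @param values numeric response vector.
#' @param covariates `data.frame` or matrix of covariates (ordinal levels
#'   as integer scores, binary as 0/1).
#' @return numeric residual vector, same length as `values`.
#' @export
covariateResidualize <- function(values, covariates) {
  cv <- encodeCovariates(covariates)
  if (is.null(cv)) return(values - mean(values))
  X <- cbind(`(Intercept)` = 1, as.matrix(cv))
  if (nrow(X) != length(values))
    stop("values and covariates have different lengths")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  qr.resid(qrX, values)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test.  When the pooled sample size is
#' at most `exactMax` the p-value is exact, by enumeration of all
#' `choose(n, n_a)` group assignments of the pooled values (ties handled
#' by average ranks); otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exactMax largest pooled size for the enumeration path
#'   (default 12).
#' @return list with `W` (the Mann-Whitney U statistic of `a`), `p`, and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
wilcoxonRankSum <- function(a, b, exactMax = 12L) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled, ties.method = "average")
  W <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (n <= exactMax) {
    splits <- combn(n, na)
    stats <- apply(splits, 2L, function(ix)
      sum(rk[ix]) - na * (na + 1) / 2)
    pLow <- mean(stats <= W)
    pHigh <- mean(stats >= W)
    p <- min(1, 2 * min(pLow, pHigh))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(rk)
    sigma2 <- (na * nb / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- W - mu
      corr <- sign(z) * 0.5
      p <- min(1, 2 * pnorm(-abs((z - corr) / sqrt(sigma2))))
    }
    method <- "normal"
  }
  list(W = W, p = p, method = method)
}

#' Test features for between-group differences
#'
#' Per feature: inverse-rank transform, residualise on covariates,
#' Wilcoxon rank-sum between the two groups on the residuals, and BH
#' adjustment across the features of this call (one call per feature
#' family - genera, EC, KO, pathway - keeps the FDR families separate).
#' Direction is the sign of the difference of median residuals
#' (group of interest minus reference).
#'
#' @param values samples-by-features numeric matrix.
#' @param group two-level factor/vector over samples; the *last* level
#'   (or `caseLevel`) is the group of interest.
#' @param covariates optional `data.frame` of covariates to residualise
#'   on.
#' @param kind label stored in the `feature_kind` column.
#' @param caseLevel which group level is the case; default the second
#'   level of `factor(group)`.
#' @return `data.frame`: `feature_id`, `feature_kind`, `W`, `p`, `fdr`,
#'   `direction`.  Constant features are reported with `NA` statistics.
#' @export
testFeatureDifferences <- function(values, group, covariates = NULL,
                                   kind = "feature", caseLevel = NULL) {
  values <- as.matrix(values)
  g <- factor(group)
  if (nlevels(g) != 2L)
    stop("group must have exactly 2 levels, got ", nlevels(g))
  if (length(g) != nrow(values))
    stop("group length does not match the sample count")
  if (is.null(caseLevel)) caseLevel <- levels(g)[2L]
  isCase <- g == caseLevel
  res <- lapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    if (length(unique(v)) == 1L)
      return(data.frame(W = NA_real_, p = NA_real_,
                        direction = NA_real_))
    tv <- inverseRankTransform(v)
    rv <- if (is.null(covariates)) tv else
      covariateResidualize(tv, covariates)
    wt <- wilcoxonRankSum(rv[isCase], rv[!isCase])
    data.frame(W = wt$W, p = wt$p,
               direction = sign(stats::median(rv[isCase]) -
                                stats::median(rv[!isCase])))
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    feature_id = colnames(values) %||% paste0("f", seq_len(ncol(values))),
    feature_kind = kind,
    W = res$W, p = res$p, fdr = bhFDR(res$p),
    direction = res$direction,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
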