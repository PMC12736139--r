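# Interaction-term variance decomposition of functional features.
#
# For a functional feature Y and a genus pair (x1, x2), two nested OLS
# models are fitted on inverse-rank-transformed values:
#   additive:     Y = a + b1*x1 + b2*x2 + e
#   interaction:  Y = a + b1*x1 + b2*x2 + b12*x1*x2 + e
# var_ind and var_int are the models' R-squared; extra_var their
# difference, i.e. the variance explained by the interaction alone.

#' Fit the additive and interaction models for one (pair, function)
#'
#' @param y functional-feature values over samples.
#' @param x1,x2 abundances of the two genera (distinct vectors).
#' @param transform inverse-rank transform all three vectors first
#'   (default TRUE, matching the shared preprocessing of the abundance
#'   tests); set FALSE when the inputs are already transformed.
#' @return one-row `data.frame`: `var_ind`, `var_int`, `extra_var`,
#'   `share` (`extra_var / var_int`, `NA` when `var_int` is 0), `p_ind`
#'   (overall F-test of the additive model, df = (2, n-3)) and
#'   `p_interaction` (nested F-test of the interaction term,
#'   df = (1, n-4)).
#' @examples
#' set.seed(1)
#' x1 <- rnorm(200); x2 <- rnorm(200)
#' fitNestedModels(x1 * x2 + rnorm(200, sd = .5), x1, x2)
#' @export
fitNestedModels <- function(y, x1, x2, transform = TRUE) {
  n <- length(y)
  if (n <= 10L) stop("need n > 10 samples, got ", n)
  if (length(x1) != n || length(x2) != n)
    stop("y, x1, x2 must have equal length")
  if (identical(x1, x2) || isTRUE(all(x1 == x2)))
    stop("x1 and x2 are identical: the interaction model is degenerate")
  if (transform) {
    y <- inverseRankTransform(y)
    x1 <- inverseRankTransform(x1)
    x2 <- inverseRankTransform(x2)
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("y is constant")
  Xind <- cbind(1, x1, x2)
  Xint <- cbind(Xind, x1 * x2)
  rssInd <- sum(lm.fit(Xind, y)$residuals^2)
  rssInt <- sum(lm.fit(Xint, y)$residuals^2)
  varInd <- 1 - rssInd / tss
  varInt <- 1 - rssInt / tss
  if (varInt < varInd) varInt <- varInd  # guard against roundoff
  extra <- varInt - varInd
  fInd <- (varInd / 2) / ((1 - varInd) / (n - 3))
  pInd <- pf(fInd, 2, n - 3, lower.tail = FALSE)
  pInt <- if (varInt >= 1) 0 else
    pf(extra / ((1 - varInt) / (n - 4)), 1, n - 4, lower.tail = FALSE)
  data.frame(var_ind = varInd, var_int = varInt, extra_var = extra,
             share = if (varInt > 0) extra / varInt else NA_real_,
             p_ind = pInd, p_interaction = pInt)
}

#' Share of explained variance attributable to the interaction
#'
#' @param result one-row `data.frame` from [fitNestedModels()], or any
#'   list with `extra_var` and `var_int`.
#' @return `extra_var / var_int`; `NA` when `var_int` is 0.
#' @export
decompositionShare <- function(result) {
  if (result$var_int == 0) return(NA_real_)
  result$extra_var / result$var_int
}

#' Decompose every (pair, function) combination with per-family FDR
#'
#' @param pairs `data.frame` with columns `taxonA`, `taxonB` (typically
#'   the differential edges).
#' @param functionTable samples-by-features numeric matrix.
#' @param abundance samples-by-taxa matrix or
#'   [CoabundanceExperiment-class] supplying the genus values.
#' @param functionKinds optional character vector over the columns of
#'   `functionTable` naming each feature's family (EC / KO / pathway);
#'   BH adjustment of `p_ind` and `p_interaction` runs within family.
#'   Defaults to a single family.
#' @param transform inverse-rank transform inputs (see
#'   [fitNestedModels()]).
#' @return `data.frame`, one row per (pair, function): `pair`,
#'   `function_id`, `function_kind`, the [fitNestedModels()] columns,
#'   `fdr_ind`, `fdr_interaction`.
#' @export
batchDecompose <- function(pairs, functionTable, abundance,
                           functionKinds = NULL, transform = TRUE) {
  m <- abundanceMatrix(abundance)
  fm <- as.matrix(functionTable)
  if (nrow(fm) != nrow(m))
    stop("function table and abundance table have different sample counts")
  fids <- colnames(fm) %||% paste0("f", seq_len(ncol(fm)))
  if (is.null(functionKinds)) functionKinds <- rep("function", ncol(fm))
  if (length(functionKinds) != ncol(fm))
    stop("functionKinds must have one entry per function column")
  missT <- setdiff(unique(c(pairs$taxonA, pairs$taxonB)), colnames(m))
  if (length(missT))
    stop("taxa absent from the abundance table: ",
         paste(missT, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    ta <- pairs$taxonA[i]; tb <- pairs$taxonB[i]
    for (j in seq_len(ncol(fm))) {
      fit <- fitNestedModels(fm[, j], m[, ta], m[, tb],
                             transform = transform)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pairName(ta, tb), taxonA = ta, taxonB = tb,
        function_id = fids[j], function_kind = functionKinds[j],
        fit, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_ind <- NA_real_
  out$fdr_interaction <- NA_real_
  for (k in unique(out$function_kind)) {
    ix <- out$function_kind == k
    out$fdr_ind[ix] <- bhFDR(out$p_ind[ix])
    out$fdr_interaction[ix] <- bhFDR(out$p_interaction[ix])
  }
  rownames(out) <- NULL
  out
}
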