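# Covariate robustness of group-associated edges via partial correlation.
#
# The full Pearson correlation matrix over [involved genera + covariates]
# is inverted; the scaled negative inverse gives the correlation of each
# genus pair conditional on everything else (all covariates and the other
# involved genera simultaneously).  A Cochran's Q test on the Fisher-Z
# scale then compares each edge's coefficient before and after
# adjustment; p > 0.05 is read as effective covariate control.

#' Pearson correlation matrix over genera and covariates
#'
#' @param genera samples-by-genera numeric matrix.
#' @param covariates `data.frame` or matrix of numerically encoded
#'   covariates (ordinal levels as integer scores, binary as 0/1), same
#'   samples in the same order.
#' @return symmetric correlation matrix over `[genera, covariates]` with
#'   unit diagonal.
#' @export
correlationMatrix <- function(genera, covariates = NULL) {
  g <- as.matrix(genera)
  X <- if (is.null(covariates)) g else {
    cv <- as.matrix(as.data.frame(lapply(as.data.frame(covariates),
                                         as.numeric)))
    rownames(cv) <- rownames(covariates)
    if (nrow(cv) != nrow(g))
      stop("genera and covariates have different sample counts")
    cbind(g, cv)
  }
  if (anyNA(X)) {
    cc <- stats::complete.cases(X)
    X <- X[cc, , drop = FALSE]
  }
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  M <- cor(X)
  (M + t(M)) / 2
}

#' Partial correlations from a full correlation matrix
#'
#' Inverts the matrix and rescales: with `Omega = M^-1`,
#' `pcor_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)` for `i != j`, and 1
#' on the diagonal.  Each entry is the correlation of variables i and j
#' conditional on all remaining variables in `M`.  A numerically singular
#' input falls back to the Moore-Penrose pseudo-inverse with a warning.
#'
#' @param M symmetric correlation (or covariance) matrix.
#' @return partial correlation matrix of the same dimension.
#' @examples
#' M <- rbind(c(1, .6, .36), c(.6, 1, .6), c(.36, .6, 1))
#' partialFromFull(M)[1, 3]  # 0: the chain x - y - z explains r_xz
#' @export
partialFromFull <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("M must be square")
  if (max(abs(M - t(M))) > 1e-8) stop("M must be symmetric")
  Om <- tryCatch(solve(M), error = function(e) {
    warning("correlation matrix is numerically singular; ",
            "using the pseudo-inverse")
    MASS::ginv(M)
  })
  d <- sqrt(pmax(diag(Om), .Machine$double.eps))
  P <- -Om / (d %o% d)
  diag(P) <- 1
  dimnames(P) <- dimnames(M)
  (P + t(P)) / 2
}

#' Cochran's Q test of an edge before vs after adjustment
#'
#' Both coefficients are Fisher-Z transformed with the shared standard
#' error `1/sqrt(n - 3)` (raw and adjusted estimates come from the same
#' samples) and compared by the same df = 1 fixed-effect Q statistic used
#' for between-group heterogeneity.
#'
#' @param rRaw,rPartial unadjusted and adjusted correlation (vectorised).
#' @param n sample count behind both estimates (> 3).
#' @return `data.frame` with `Q`, `I2`, `p_adjustment`, `robust`
#'   (`p_adjustment > 0.05`).
#' @export
adjustmentQTest <- function(rRaw, rPartial, n) {
  if (any(n <= 3)) stop("n must be > 3")
  se <- 1 / sqrt(n - 3)
  het <- betweenGroupHeterogeneity(fisherZ(rRaw), se, fisherZ(rPartial), se)
  data.frame(Q = het$Q, I2 = het$I2, p_adjustment = het$hetero_p,
             robust = het$hetero_p > 0.05)
}

#' Adjust a set of edges for covariates and test robustness
#'
#' For the genera incident to the supplied edges, builds the full
#' correlation matrix over genera plus covariates on the (optionally
#' zero-replaced, log-transformed) abundances, converts it to partial
#' correlations, and runs [adjustmentQTest()] per edge.
#'
#' @param x a [CoabundanceExperiment-class] or samples-by-taxa matrix of
#'   relative abundances.
#' @param edges `data.frame` with columns `taxonA`, `taxonB` (e.g. the
#'   differential calls).
#' @param covariates `data.frame` of numerically encodable covariates
#'   (defaults to the covariate columns of `sampleData(x)` when `x` is an
#'   experiment).
#' @param logTransform correlate log abundances (after zero replacement)
#'   rather than raw relative abundances.
#' @return `data.frame`, one row per edge: `pair`, `taxonA`, `taxonB`,
#'   `r_raw`, `r_partial`, `Q`, `p_adjustment`, `robust`.
#' @export
adjustEdges <- function(x, edges, covariates = NULL, logTransform = TRUE) {
  m <- abundanceMatrix(x)
  if (is.null(covariates) && is(x, "CoabundanceExperiment")) {
    sd <- sampleData(x)
    covariates <- sd[, intersect(metadataCovariates(), colnames(sd)),
                     drop = FALSE]
  }
  genera <- sort(unique(c(edges$taxonA, edges$taxonB)))
  miss <- setdiff(genera, colnames(m))
  if (length(miss))
    stop("edge genera absent from the abundance table: ",
         paste(miss, collapse = ", "))
  g <- m[, genera, drop = FALSE]
  if (logTransform) g <- log(replaceZeros(closeRows(m))[, genera,
                                                        drop = FALSE])
  covariates <- encodeCovariates(covariates)
  M <- correlationMatrix(g, covariates)
  P <- partialFromFull(M)
  n <- nrow(g)
  rRaw <- M[cbind(edges$taxonA, edges$taxonB)]
  rPartial <- P[cbind(edges$taxonA, edges$taxonB)]
  qt <- adjustmentQTest(rRaw, rPartial, n)
  data.frame(pair = pairName(edges$taxonA, edges$taxonB),
             taxonA = edges$taxonA, taxonB = edges$taxonB,
             r_raw = rRaw, r_partial = rPartial,
             Q = qt$Q, p_adjustment = qt$p_adjustment,
             robust = qt$robust, stringsAsFactors = FALSE)
}

# map metadata covariates to a numeric design: ordinal factors/characters
# become integer scores by level order, logicals and binaries 0/1
encodeCovariates <- function(covariates) {
  if (is.null(covariates) || !NCOL(covariates)) return(NULL)
  df <- as.data.frame(covariates)
  enc <- lapply(df, function(col) {
    if (is.numeric(col)) return(col)
    if (is.logical(col)) return(as.numeric(col))
    if (is.factor(col)) return(as.numeric(col) - 1)
    as.numeric(factor(col)) - 1
  })
  out <- as.data.frame(enc)
  rownames(out) <- rownames(df)
  out
}
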