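# Latent correlation inference for compositional data.
#
# Relative abundances only identify the covariance of log-basis abundances
# up to the compositional null direction (the all-ones vector): naive
# correlations of relative abundances are spurious.  The estimator below
# fits a sparse, positive-semidefinite latent covariance by minimising
#
#   1/2 || P (Sigma - S) P ||_F^2  +  lambda * sum_{i<j} |sigma_ij|
#
# over symmetric PSD Sigma, where S is the empirical covariance of
# log-composition and P = I - (1/p) 11' projects out the null direction.

#' Replace zeros in a relative-abundance table
#'
#' The latent-correlation estimator needs strictly positive compositions.
#' Zeros are replaced with half of the smallest non-zero value observed
#' anywhere in the table (a multiplicative-replacement simplification),
#' then each row is re-closed to sum 1.
#'
#' @param x a [CoabundanceExperiment-class] or samples-by-taxa matrix of
#'   relative abundances.
#' @return object of the same class as `x`, strictly positive, rows
#'   closed.
#' @export
replaceZeros <- function(x) {
  m <- abundanceMatrix(x)
  allZero <- rowSums(m) == 0
  if (any(allZero))
    stop("sample(s) with all-zero abundance: ",
         paste(rownames(m)[allZero], collapse = ", "))
  if (any(m > 0 & m < .Machine$double.eps))
    warning("values below machine precision treated as positive")
  if (any(m == 0)) {
    eps <- 0.5 * min(m[m > 0])
    m[m == 0] <- eps
  }
  m <- closeRows(m)
  if (is(x, "CoabundanceExperiment"))
    CoabundanceExperiment(m, sampleData = sampleData(x), relative = TRUE)
  else m
}

# consensus ADMM on the penalised projected least-squares objective.
# X carries the quadratic term; Z1 the PSD constraint (eigenvalue
# truncation); Z2 the off-diagonal soft-thresholding.
.cclassoADMM <- function(S, lambda, rho = 1, tol = 1e-6, maxIter = 2000L) {
  p <- nrow(S)
  Pm <- diag(p) - matrix(1 / p, p, p)
  PSP <- Pm %*% S %*% Pm
  X <- S; Z1 <- S; Z2 <- S
  U1 <- matrix(0, p, p); U2 <- matrix(0, p, p)
  soft <- function(M, t) {
    d <- diag(M)
    M <- sign(M) * pmax(abs(M) - t, 0)
    diag(M) <- d
    M
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    # quadratic step has a closed form: the normal equation
    # P X P + 2 rho X = A splits along the eigenspaces of P
    A <- PSP + rho * (Z1 - U1 + Z2 - U2)
    PAP <- Pm %*% A %*% Pm
    X <- A / (2 * rho) + PAP * (1 / (1 + 2 * rho) - 1 / (2 * rho))
    X <- (X + t(X)) / 2
    e <- eigen(X + U1, symmetric = TRUE)
    Z1n <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    Z1n <- (Z1n + t(Z1n)) / 2
    Z2n <- soft(X + U2, lambda / rho)
    delta <- max(abs(Z1n - Z1), abs(Z2n - Z2), abs(X - Z1n), abs(X - Z2n))
    Z1 <- Z1n; Z2 <- Z2n
    U1 <- U1 + X - Z1
    U2 <- U2 + X - Z2
    if (delta < tol) { converged <- TRUE; break }
  }
  list(Sigma = Z2, iterations = it, converged = converged)
}

#' Fit the L1-penalised latent correlation of a composition
#'
#' Estimates the correlation matrix of latent log-basis abundances from a
#' strictly positive relative-abundance table, by operator splitting
#' (ADMM) over the penalised projected least-squares objective: a
#' closed-form quadratic step, projection onto the PSD cone by eigenvalue
#' truncation, and elementwise soft-thresholding of the off-diagonal
#' entries.  The estimate is rescaled to a correlation matrix once, at
#' convergence.
#'
#' @param x a [CoabundanceExperiment-class] or samples-by-taxa matrix of
#'   strictly positive relative abundances (run [replaceZeros()] first if
#'   needed).
#' @param lambda non-negative L1 penalty on off-diagonal entries.
#' @param tol max-norm convergence tolerance between successive iterates.
#' @param maxIter iteration cap; hitting it flags the result as
#'   non-converged (with a warning) rather than failing.
#' @param group,region optional stratum labels carried into the result.
#' @return a [LatentCorrelation-class].
#' @examples
#' set.seed(1)
#' w <- exp(matrix(rnorm(200 * 4), 200, 4))
#' comp <- w / rowSums(w)
#' colnames(comp) <- paste0("g", 1:4)
#' fitLatentCorrelation(comp, lambda = 0.05)
#' @export
fitLatentCorrelation <- function(x, lambda = 0.05, tol = 1e-6,
                                 maxIter = 2000L, group = "",
                                 region = "") {
  m <- abundanceMatrix(x)
  if (any(m <= 0))
    stop("composition must be strictly positive; run replaceZeros() first")
  if (lambda < 0) stop("lambda must be >= 0")
  if (nrow(m) < 4L) stop("need at least 4 samples, got ", nrow(m))
  S <- cov(log(m))
  fit <- .cclassoADMM(S, lambda = lambda, tol = tol,
                      maxIter = as.integer(maxIter))
  if (!fit$converged)
    warning("latent-correlation solver did not converge in ", maxIter,
            " iterations (stratum ", group, ":", region, ")")
  Sg <- fit$Sigma
  d <- sqrt(pmax(diag(Sg), .Machine$double.eps))
  R <- Sg / (d %o% d)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  R[R > 1] <- 1; R[R < -1] <- -1
  # guard against tiny negative eigenvalues introduced by the rescaling
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    R <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    d2 <- sqrt(pmax(diag(R), .Machine$double.eps))
    R <- R / (d2 %o% d2)
    diag(R) <- 1
    R <- (R + t(R)) / 2
  }
  dimnames(R) <- list(colnames(m), colnames(m))
  new("LatentCorrelation", rho = R, lambda = lambda,
      n = nrow(m), group = group, region = region,
      converged = fit$converged, iterations = as.integer(fit$iterations))
}

#' Select the penalty by k-fold cross-validation
#'
#' Picks the grid value minimising the mean held-out projected
#' least-squares loss `1/2 ||P (Sigma_train - S_test) P||_F^2` across
#' folds.  Fold assignment is deterministic given `seed`.
#'
#' @inheritParams fitLatentCorrelation
#' @param grid non-empty numeric vector of candidate penalties.
#' @param kFolds number of folds (>= 2).
#' @param seed integer controlling the fold split.
#' @return the selected penalty (a scalar from `grid`).
#' @export
selectLambda <- function(x, grid = c(0.01, 0.02, 0.05, 0.1, 0.2),
                         kFolds = 5L, seed = 1L, tol = 1e-6,
                         maxIter = 2000L) {
  m <- abundanceMatrix(x)
  if (!length(grid)) stop("penalty grid must be non-empty")
  if (kFolds < 2L) stop("kFolds must be >= 2")
  n <- nrow(m)
  if (n < kFolds) stop("fewer samples (", n, ") than folds (", kFolds, ")")
  if (length(grid) == 1L) return(grid)
  p <- ncol(m)
  Pm <- diag(p) - matrix(1 / p, p, p)
  folds <- withSeed(seed, sample(rep_len(seq_len(kFolds), n)))
  L <- log(m)
  loss <- matrix(NA_real_, kFolds, length(grid))
  for (f in seq_len(kFolds)) {
    trainS <- cov(L[folds != f, , drop = FALSE])
    testS <- cov(L[folds == f, , drop = FALSE])
    for (g in seq_along(grid)) {
      fit <- .cclassoADMM(trainS, lambda = grid[g], tol = tol,
                          maxIter = as.integer(maxIter))
      D <- Pm %*% (fit$Sigma - testS) %*% Pm
      loss[f, g] <- 0.5 * sum(D * D)
    }
  }
  grid[which.min(colMeans(loss))]
}

#' Flatten a latent correlation matrix into per-pair edge estimates
#'
#' @param lc a [LatentCorrelation-class].
#' @return `data.frame` with one row per unordered taxon pair
#'   (`p*(p-1)/2` rows): `taxonA`, `taxonB`, `pair`, `r`, `n`, `group`,
#'   `region`.
#' @export
edgesFromMatrix <- function(lc) {
  stopifnot(is(lc, "LatentCorrelation"))
  R <- lc@rho
  ids <- rownames(R)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  df <- data.frame(
    taxonA = ids[ut[, 1L]],
    taxonB = ids[ut[, 2L]],
    r = R[ut],
    n = lc@n,
    group = lc@group,
    region = lc@region,
    stringsAsFactors = FALSE)
  df$pair <- pairName(df$taxonA, df$taxonB)
  df[, c("pair", "taxonA", "taxonB", "r", "n", "group", "region")]
}
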