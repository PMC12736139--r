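#' Container for a compositional abundance table with sample annotations
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' taxa-by-samples relative-abundance (or count) assay named
#' `"abundance"`, with sample metadata (group, region, covariates) in
#' `colData`.  The on-disk orientation (samples in rows) used by
#' [readAbundance()] is transposed on import; [relAbundance()] hands the
#' samples-by-taxa matrix back to analysis code.
#'
#' @slot relative logical scalar; `TRUE` when the assay rows are closed
#'   compositions (each sample sums to 1), `FALSE` for raw counts.
#' @export
setClass("CoabundanceExperiment",
         contains = "SummarizedExperiment",
         slots = c(relative = "logical"),
         prototype = prototype(relative = TRUE))

setValidity("CoabundanceExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    a <- assay(object, "abundance")
    if (anyNA(a)) msg <- c(msg, "abundance values must not be NA")
    else if (any(a < 0)) msg <- c(msg, "abundance values must be >= 0")
    else if (isTRUE(object@relative) && ncol(a) > 0) {
      cs <- colSums(a)
      off <- abs(cs - 1) > 1e-6
      if (any(off))
        msg <- c(msg, paste0("relative abundances must sum to 1 per sample; ",
                             "off by > 1e-6: ",
                             paste(colnames(a)[off][seq_len(min(3, sum(off)))],
                                   collapse = ", ")))
    }
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate taxon ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (length(object@relative) != 1L)
    msg <- c(msg, "'relative' must be a logical scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a CoabundanceExperiment
#'
#' @param abundance numeric samples-by-taxa matrix (the natural orientation
#'   of a tab-separated abundance table).
#' @param sampleData `data.frame` of per-sample annotations, one row per
#'   sample, matched to `rownames(abundance)` (by name if rownames are
#'   present, else by position).
#' @param relative logical; are the rows closed compositions?
#' @return a [CoabundanceExperiment-class] object.
#' @examples
#' m <- matrix(c(.2, .8, .5, .5), 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("gA", "gB")))
#' CoabundanceExperiment(m)
#' @export
CoabundanceExperiment <- function(abundance, sampleData = NULL,
                                  relative = TRUE) {
  abundance <- abundanceMatrix(abundance)
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = rownames(abundance))
  } else {
    sd <- as.data.frame(sampleData)
    if (!is.null(rownames(abundance)) && !is.null(rownames(sd)) &&
        !identical(rownames(sd), rownames(abundance))) {
      if (!all(rownames(abundance) %in% rownames(sd)))
        stop("sampleData is missing rows for sample(s): ",
             paste(setdiff(rownames(abundance), rownames(sd)),
                   collapse = ", "))
      sd <- sd[rownames(abundance), , drop = FALSE]
    }
    DataFrame(sd, row.names = rownames(abundance))
  }
  new("CoabundanceExperiment",
      SummarizedExperiment(assays = list(abundance = t(abundance)),
                           colData = cd),
      relative = relative)
}

#' Latent correlation matrix for one (group, region) stratum
#'
#' Result of [fitLatentCorrelation()]: the estimated correlation matrix of
#' latent log-basis abundances, with the penalty and sample size that
#' produced it.
#'
#' @slot rho p-by-p correlation matrix (symmetric, unit diagonal, PSD
#'   within numerical tolerance), dimnames = taxon ids.
#' @slot lambda non-negative L1 penalty weight used.
#' @slot n integer sample count behind the estimate.
#' @slot group,region character labels of the stratum ("" when unset).
#' @slot converged logical; FALSE when the solver hit its iteration cap.
#' @slot iterations iterations used by the solver.
#' @export
setClass("LatentCorrelation",
         slots = c(rho = "matrix", lambda = "numeric", n = "integer",
                   group = "character", region = "character",
                   converged = "logical", iterations = "integer"))

setValidity("LatentCorrelation", function(object) {
  r <- object@rho
  msg <- character()
  if (nrow(r) != ncol(r)) msg <- c(msg, "rho must be square")
  else {
    if (max(abs(r - t(r))) > 1e-8) msg <- c(msg, "rho must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) msg <- c(msg, "rho diagonal must be 1")
    if (max(abs(r)) > 1 + 1e-8) msg <- c(msg, "|rho| must be <= 1")
    ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      msg <- c(msg, sprintf("rho must be PSD (min eigenvalue %.3g)", ev))
  }
  if (object@n < 4L) msg <- c(msg, "n must be >= 4")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth behind a synthetic dataset
#'
#' @slot latentCorr named list of p-by-p latent correlation matrices, one
#'   per `group:region` stratum.
#' @slot latentLog samples-by-taxa matrix of the latent (pre-closure)
#'   log-abundances actually drawn.
#' @slot differentialPairs data.frame with columns `taxonA`, `taxonB`,
#'   `rhoA`, `rhoB`: pairs planted with group-specific correlation.
#' @slot functionEffects data.frame with columns `functionId`, `taxonA`,
#'   `taxonB`, `beta1`, `beta2`, `beta12`, `noiseSd`.
#' @slot keystoneTaxa character vector of taxa planted as keystones.
#' @export
setClass("GroundTruth",
         slots = c(latentCorr = "list", latentLog = "matrix",
                   differentialPairs = "data.frame",
                   functionEffects = "data.frame",
                   keystoneTaxa = "character"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  for (nm in names(object@latentCorr)) {
    R <- object@latentCorr[[nm]]
    if (max(abs(R - t(R))) > 1e-8)
      msg <- c(msg, paste0("latentCorr[", nm, "] not symmetric"))
    if (max(abs(diag(R) - 1)) > 1e-8)
      msg <- c(msg, paste0("latentCorr[", nm, "] diagonal not 1"))
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      msg <- c(msg, sprintf("latentCorr[%s] not PSD (min eig %.3g)", nm, ev))
  }
  dp <- object@differentialPairs
  if (nrow(dp) && any(abs(c(dp$rhoA, dp$rhoB)) > 1))
    msg <- c(msg, "planted |rho| must be <= 1")
  if (length(msg)) msg else TRUE
})

#' A fully simulated study: abundances, metadata, functions and truth
#'
#' @slot experiment the [CoabundanceExperiment-class] with group, region
#'   and covariates in `colData`.
#' @slot functions samples-by-features matrix of simulated functional
#'   abundances (may have zero columns).
#' @slot truth the [GroundTruth-class] used to generate the data.
#' @slot seed integer seed the dataset was generated from.
#' @slot config the simulation configuration list (see [simConfig()]).
#' @export
setClass("SyntheticDataset",
         slots = c(experiment = "CoabundanceExperiment",
                   functions = "matrix", truth = "GroundTruth",
                   seed = "integer", config = "list"))

setMethod("show", "CoabundanceExperiment", function(object) {
  cat("CoabundanceExperiment:", nrow(object), "taxa x",
      ncol(object), "samples",
      if (object@relative) "(relative abundances)\n" else "(counts)\n")
  cd <- colData(object)
  if (ncol(cd))
    cat("  sample annotations:", paste(colnames(cd), collapse = ", "), "\n")
})

setMethod("show", "LatentCorrelation", function(object) {
  p <- nrow(object@rho)
  nz <- sum(abs(object@rho[upper.tri(object@rho)]) > 0)
  cat(sprintf("LatentCorrelation: %d taxa, n = %d, lambda = %.4g\n",
              p, object@n, object@lambda))
  if (nzchar(object@group) || nzchar(object@region))
    cat(sprintf("  stratum: group = %s, region = %s\n",
                object@group, object@region))
  cat(sprintf("  %d of %d off-diagonal pairs non-zero; converged: %s (%d iterations)\n",
              nz, p * (p - 1) / 2, object@converged, object@iterations))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset (seed", object@seed, ")\n")
  show(object@experiment)
  cat(" ", ncol(object@functions), "functional features;",
      nrow(object@truth@differentialPairs), "planted differential pairs;",
      length(object@truth@keystoneTaxa), "planted keystones\n")
})
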