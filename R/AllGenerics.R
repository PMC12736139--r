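#' Extract the samples-by-taxa abundance matrix
#'
#' @param x a [CoabundanceExperiment-class].
#' @return numeric matrix, samples in rows, taxa in columns.
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' @rdname relAbundance
setMethod("relAbundance", "CoabundanceExperiment",
          function(x) t(assay(x, "abundance")))

#' Sample annotations as a data.frame
#'
#' @param x a [CoabundanceExperiment-class].
#' @return `data.frame`, one row per sample.
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname sampleData
setMethod("sampleData", "CoabundanceExperiment",
          function(x) as.data.frame(colData(x)))

#' Taxon identifiers
#'
#' @param x a [CoabundanceExperiment-class] or [LatentCorrelation-class].
#' @return character vector of taxon ids.
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))

#' @rdname taxonIds
setMethod("taxonIds", "CoabundanceExperiment", function(x) rownames(x))

#' @rdname taxonIds
setMethod("taxonIds", "LatentCorrelation", function(x) rownames(x@rho))

#' Per-taxon prevalence (fraction of samples with abundance > 0)
#'
#' @param x a [CoabundanceExperiment-class] or samples-by-taxa matrix.
#' @return named numeric vector of presence fractions.
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))

#' @rdname prevalence
setMethod("prevalence", "ANY", function(x) taxonPrevalence(abundanceMatrix(x)))

#' Drop taxa below a prevalence threshold
#'
#' Retains taxa whose presence fraction is at least `minPrevalence`
#' (inclusive).  On relative-abundance input the surviving rows are
#' re-closed to sum 1.
#'
#' @param x a [CoabundanceExperiment-class] or samples-by-taxa matrix.
#' @param minPrevalence minimum presence fraction in `[0, 1]`.
#' @param verbose log the dropped taxa via `message()`.
#' @return object of the same class as `x`, possibly with fewer taxa.
#' @export
setGeneric("filterByPrevalence",
           function(x, minPrevalence = 0.1, verbose = FALSE)
             standardGeneric("filterByPrevalence"))

#' @rdname filterByPrevalence
setMethod("filterByPrevalence", "matrix",
          function(x, minPrevalence = 0.1, verbose = FALSE) {
  stopifnot(minPrevalence >= 0, minPrevalence <= 1)
  keep <- taxonPrevalence(x) >= minPrevalence
  if (verbose && any(!keep))
    message("dropping ", sum(!keep), " taxa below prevalence ",
            minPrevalence, ": ",
            paste(head(colnames(x)[!keep], 10), collapse = ", "),
            if (sum(!keep) > 10) ", ..." else "")
  x[, keep, drop = FALSE]
})

#' @rdname filterByPrevalence
setMethod("filterByPrevalence", "CoabundanceExperiment",
          function(x, minPrevalence = 0.1, verbose = FALSE) {
  m <- filterByPrevalence(relAbundance(x), minPrevalence, verbose)
  if (x@relative) m <- closeRows(m)
  CoabundanceExperiment(m, sampleData = sampleData(x),
                        relative = x@relative)
})

#' Correlation matrix slot of a LatentCorrelation
#'
#' @param x a [LatentCorrelation-class].
#' @return the p-by-p correlation matrix.
#' @export
setGeneric("latentRho", function(x) standardGeneric("latentRho"))

#' @rdname latentRho
setMethod("latentRho", "LatentCorrelation", function(x) x@rho)
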