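# Tab-separated readers/writers for every artifact the pipeline touches.
# Dialect: UTF-8, "." decimal, no quoting; scientific notation accepted on
# read.  Readers are strict: a non-numeric cell is an error with its
# coordinates, never silently NA-filled.

# strict numeric samples-by-features TSV (header = feature ids, first
# column = sample id)
.readMatrixTSV <- function(path, what = "feature") {
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    fill = FALSE, blank.lines.skip = FALSE)
  if (ncol(raw) < 2L)
    stop("expected at least a sample-id column and one ", what,
         " column in ", path)
  sampleIds <- raw[[1L]]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample id(s) in ", path, ": ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  ids <- colnames(raw)[-1L]
  if (anyDuplicated(ids))
    stop("duplicate ", what, " id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(raw), length(ids),
              dimnames = list(sampleIds, ids))
  for (j in seq_along(ids)) {
    col <- raw[[j + 1L]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !(col %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (sample '%s'), column '%s' in %s",
                   col[bad[1L]], bad[1L], sampleIds[bad[1L]], ids[j], path))
    if (anyNA(v))
      stop(sprintf("missing value at row %d, column '%s' in %s",
                   which(is.na(v))[1L], ids[j], path))
    m[, j] <- v
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at sample '%s', column '%s' in %s",
                 rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]], path))
  m
}

.writeMatrixTSV <- function(m, path, idColumn = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a genus abundance table with prevalence filtering
#'
#' Reads a tab-separated samples-by-taxa table (header row of taxon ids,
#' first column the sample id), drops taxa whose prevalence falls strictly
#' below `minPrevalence` (the comparison is inclusive: a taxon at exactly
#' the threshold is retained), and on relative data re-closes each row to
#' sum 1 after filtering.
#'
#' @param path TSV file path.
#' @param minPrevalence minimum fraction of samples with abundance > 0;
#'   default 0 keeps everything.
#' @param relative logical; treat the values as closed compositions
#'   (re-closed after filtering) rather than raw counts.
#' @param verbose log dropped taxa.
#' @return a [CoabundanceExperiment-class].
#' @export
readAbundance <- function(path, minPrevalence = 0, relative = TRUE,
                          verbose = FALSE) {
  m <- .readMatrixTSV(path, what = "taxon")
  m <- filterByPrevalence(m, minPrevalence, verbose = verbose)
  if (relative) m <- closeRows(m)
  CoabundanceExperiment(m, relative = relative)
}

#' Write the abundance assay of an experiment as TSV
#'
#' @param x a [CoabundanceExperiment-class] or samples-by-taxa matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeAbundance <- function(x, path) {
  .writeMatrixTSV(abundanceMatrix(x), path)
}

# covariate columns expected by the adjustment/testing stages
metadataCovariates <- function() {
  c("age", "sex", "smoking", "alcohol", "physical_activity",
    "grains", "vegetables", "fruits", "dairy", "animal_products",
    "beans_nuts")
}

#' Read sample metadata
#'
#' Expects a TSV with a `sample_id` column plus `group`, `region` and the
#' covariates used for adjustment (age, sex, smoking, alcohol,
#' physical_activity and six dietary quantities in grams/day).  Missing
#' annotation columns are tolerated with a warning so partial tables can
#' still drive the network stages.
#'
#' @param path TSV file path.
#' @return `data.frame` with rownames = sample ids.
#' @export
readSampleMetadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, fill = FALSE,
                   stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("metadata must contain a 'sample_id' column: ", path)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  expected <- c("group", "region", metadataCovariates())
  miss <- setdiff(expected, colnames(df))
  if (length(miss))
    warning("metadata is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname readSampleMetadata
#' @param metadata `data.frame` with rownames = sample ids.
#' @export
writeSampleMetadata <- function(metadata, path) {
  df <- data.frame(sample_id = rownames(metadata), metadata,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a predicted-function abundance table
#'
#' Same layout as the abundance table, with EC / KO / pathway identifiers
#' in the header.
#'
#' @param path TSV file path.
#' @param minPrevalence drop features present in fewer than this fraction
#'   of samples (inclusive threshold).
#' @return samples-by-features numeric matrix.
#' @export
readFunctionTable <- function(path, minPrevalence = 0) {
  m <- .readMatrixTSV(path, what = "function")
  filterByPrevalence(m, minPrevalence)
}

#' @rdname readFunctionTable
#' @param m samples-by-features matrix.
#' @export
writeFunctionTable <- function(m, path) .writeMatrixTSV(m, path)

#' Write / read a differential-edge table
#'
#' The written TSV carries, per genus pair, the pooled Fisher-Z effects
#' and standard errors of both groups, the between-group Cochran's Q,
#' I-squared and heterogeneity p, per-group FDR, and the differential /
#' direction-change flags.  Pair labels use [pairName()] (lexicographic
#' member order).
#'
#' @param edges `data.frame` as produced by [differentialEdges()].
#' @param path output TSV.
#' @return the path, invisibly (for the writer); the `data.frame` for the
#'   reader.
#' @export
writeEdgeTable <- function(edges, path) {
  cols <- c("pair", "TE_A", "TE_B", "seTE_A", "seTE_B", "groupA", "groupB",
            "Q", "I2", "hetero_p", "fdr_A", "fdr_B",
            "is_differential", "direction_change")
  if (nrow(edges) == 0) {
    empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                    cols))
    write.table(empty, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    return(invisible(path))
  }
  miss <- setdiff(cols, colnames(edges))
  if (length(miss))
    stop("edge table is missing column(s): ", paste(miss, collapse = ", "))
  write.table(edges[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeEdgeTable
#' @export
readEdgeTable <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, fill = FALSE,
                   stringsAsFactors = FALSE)
  num <- c("TE_A", "TE_B", "seTE_A", "seTE_B", "Q", "I2", "hetero_p",
           "fdr_A", "fdr_B")
  for (cn in intersect(num, colnames(df))) df[[cn]] <- as.numeric(df[[cn]])
  for (cn in intersect(c("is_differential", "direction_change"),
                       colnames(df)))
    df[[cn]] <- as.logical(df[[cn]])
  df
}

#' Export a significant co-abundance network
#'
#' Keeps edges with `fdr < fdrCut`; nodes are the taxa incident to at
#' least one retained edge.  Edge attributes: `TE`, `seTE` and `sign`
#' (`"+"` / `"-"` by the direction of the pooled effect); optional node
#' attribute `phylum`.
#'
#' @param pooled pooled-edge `data.frame` from [poolEdges()] (columns
#'   `taxonA`, `taxonB`, `TE`, `seTE`, `fdr`).
#' @param fdrCut FDR threshold (default 0.05).
#' @param path output file.
#' @param format `"graphml"` or `"json"` (node-link).
#' @param phylum optional named character vector mapping taxon to phylum.
#' @return the [igraph::graph] object, invisibly.
#' @export
exportNetwork <- function(pooled, fdrCut = 0.05, path,
                          format = c("graphml", "json"), phylum = NULL) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unknown network format; supported: graphml, json"))
  keep <- pooled[!is.na(pooled$fdr) & pooled$fdr < fdrCut, , drop = FALSE]
  if (nrow(keep)) {
    el <- cbind(keep$taxonA, keep$taxonB)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::E(g)$TE <- keep$TE
    igraph::E(g)$seTE <- keep$seTE
    igraph::E(g)$sign <- ifelse(keep$TE >= 0, "+", "-")
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  }
  if (!is.null(phylum) && igraph::vcount(g) > 0)
    igraph::V(g)$phylum <-
      unname(phylum[igraph::V(g)$name])
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    nodes <- if (igraph::vcount(g)) {
      nd <- data.frame(id = igraph::V(g)$name, stringsAsFactors = FALSE)
      if (!is.null(phylum)) nd$phylum <- unname(phylum[nd$id])
      nd
    } else data.frame(id = character(0))
    links <- if (igraph::ecount(g)) {
      data.frame(source = keep$taxonA, target = keep$taxonB,
                 TE = keep$TE, seTE = keep$seTE,
                 sign = ifelse(keep$TE >= 0, "+", "-"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(source = character(0), target = character(0))
    }
    jsonlite::write_json(list(nodes = nodes, links = links), path,
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(g)
}

#' Serialize / load the ground truth of a synthetic dataset as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON file path.
#' @return the path (writer) or a [GroundTruth-class] (reader).  The
#'   reader does not restore `latentLog` (it is data-sized and
#'   reconstructible from the seed), only the planted structure.
#' @export
writeGroundTruth <- function(truth, path) {
  obj <- list(
    latentCorr = lapply(truth@latentCorr, function(m)
      list(taxa = rownames(m), values = unname(m))),
    differentialPairs = truth@differentialPairs,
    functionEffects = truth@functionEffects,
    keystoneTaxa = truth@keystoneTaxa)
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lc <- lapply(obj$latentCorr, function(e) {
    m <- as.matrix(e$values)
    dimnames(m) <- list(e$taxa, e$taxa)
    m
  })
  new("GroundTruth", latentCorr = lc,
      latentLog = matrix(numeric(0), 0, 0),
      differentialPairs = as.data.frame(obj$differentialPairs),
      functionEffects = as.data.frame(obj$functionEffects),
      keystoneTaxa = as.character(obj$keystoneTaxa %||% character(0)))
}

#' Read a simulation or pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
readConfigYAML <- function(path) yaml::read_yaml(path)

#' @rdname readConfigYAML
#' @param config named list.
#' @export
writeConfigYAML <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
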