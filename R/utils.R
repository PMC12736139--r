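# internal helpers shared across stages

# Run expr with a private RNG stream; the caller's .Random.seed is
# untouched.  seed = NULL runs expr against the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# close each row to sum 1
closeRows <- function(x) {
  rs <- rowSums(x)
  if (any(rs <= 0)) {
    stop("cannot close rows with non-positive sum: sample(s) ",
         paste(rownames(x)[rs <= 0], collapse = ", "))
  }
  sweep(x, 1L, rs, "/")
}

# centered log-ratio of a strictly positive composition (samples x taxa)
clr <- function(x) {
  if (any(x <= 0)) stop("clr requires strictly positive values")
  lx <- log(x)
  sweep(lx, 1L, rowMeans(lx), "-")
}

#' Canonical unordered pair name
#'
#' Renders a taxon pair as `"A-B"` with the two members in lexicographic
#' order, so that pair identity is independent of orientation.
#'
#' @param a,b character vectors of taxon names (recycled to common length).
#' @return character vector of pair labels.
#' @examples
#' pairName("Sporobacter", "Alistipes")  # "Alistipes-Sporobacter"
#' @export
pairName <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- b < a
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste0(lo, "-", hi)
}

# split "A-B" back into members (first "-" in sorted order is ambiguous
# only if taxon names themselves contain "-"; the writers forbid that)
splitPair <- function(pair) {
  parts <- strsplit(pair, "-", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed pair label(s): ",
                     paste(pair[bad], collapse = ", "))
  do.call(rbind, parts)
}

# fraction of samples in which each taxon is present (> 0)
taxonPrevalence <- function(mat) colMeans(mat > 0)

# coerce the numeric abundance input (samples x taxa) out of whatever
# container the user handed us
abundanceMatrix <- function(x) {
  if (is(x, "CoabundanceExperiment")) return(relAbundance(x))
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(colnames(x)))
      colnames(x) <- paste0("taxon", seq_len(ncol(x)))
    if (is.null(rownames(x)))
      rownames(x) <- paste0("sample", seq_len(nrow(x)))
    return(x)
  }
  if (is.data.frame(x)) return(abundanceMatrix(as.matrix(x)))
  stop("expected a samples-by-taxa matrix or a CoabundanceExperiment, got ",
       class(x)[1])
}

# two-sample Kolmogorov-Smirnov statistic, tie-safe, no p-value machinery
ksStat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  w <- c(x, y)
  z <- cumsum(ifelse(order(w) <= nx, 1 / nx, -1 / ny))
  ws <- sort(w)
  keep <- c(diff(ws) != 0, TRUE)
  max(abs(z[keep]))
}

# Benjamini-Hochberg with input validation (delegates to p.adjust)
#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, capped at 1, returned in the input order.
#' NA entries propagate as NA and do not count toward the family size.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted values, same length and order.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.04))
#' @export
bhFDR <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values outside [0, 1]: ",
         paste(format(p[ok][p[ok] < 0 | p[ok] > 1]), collapse = ", "))
  }
  p.adjust(p, method = "BH")
}
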