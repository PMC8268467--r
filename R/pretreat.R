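#' Bayesian-multiplicative zero replacement
#'
#' Replaces zero counts in a compositional count matrix by small positive
#' values derived from a Bayes-Laplace prior, with a compensating
#' multiplicative shrinkage of the non-zero parts so that each row keeps its
#' total "mass" interpretation.  Rows without zeros are returned unchanged.
#'
#' For a row with total count \eqn{n} over \eqn{m} parts, a zero in column
#' \eqn{j} becomes \eqn{t \cdot s / (n + s)} with prior weights
#' \eqn{t = 1/m} and prior strength \eqn{s = m} (the Bayes-Laplace choice),
#' and each non-zero entry is multiplied by one minus the total mass assigned
#' to that row's zeros.  Replacement is applied independently per row
#' (per sample).
#'
#' @param counts numeric matrix of non-negative counts, samples in rows and
#'   features (e.g. OTUs) in columns.
#' @return a matrix of the same dimensions with strictly positive entries.
#' @examples
#' bm_replace(rbind(c(0, 2, 2), c(5, 3, 2)))
#' @seealso [closure()], [clr()], [pretreat()]
#' @export
bm_replace <- function(counts) {
  counts <- as_count_matrix(counts)
  m <- ncol(counts)
  zero_rows <- which(rowSums(counts > 0) == 0L)
  if (length(zero_rows) > 0L) {
    stop("degenerate sample: row(s) ",
         paste(rownames(counts)[zero_rows], collapse = ", "),
         " contain only zeros")
  }
  out <- counts
  has_zero <- which(rowSums(counts == 0) > 0L)
  for (i in has_zero) {
    x <- counts[i, ]
    n <- sum(x)
    z <- x == 0
    # Bayes-Laplace prior: t = 1/m, s = m, so each zero receives 1/(n + m)
    repl <- (1 / m) * (m / (n + m))
    x[z] <- repl
    x[!z] <- x[!z] * (1 - sum(z) * repl)
    out[i, ] <- x
  }
  out
}

#' Closure (constant-sum scaling) of a positive matrix
#'
#' Rescales every row of a strictly positive matrix so that its parts sum to
#' the constant `k`.  Closure makes the compositional nature of count data
#' explicit; downstream log-ratio transforms are invariant to it.
#'
#' @param x numeric matrix with strictly positive entries (run
#'   [bm_replace()] first if the data contain zeros).
#' @param k positive closure constant; 100 gives percentages.
#' @return matrix whose rows each sum to `k`.
#' @examples
#' closure(matrix(c(1, 3), 1, 2))          # 25, 75
#' @export
closure <- function(x, k = 100) {
  x <- as.matrix(x)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("`k` must be a single positive number")
  if (any(x <= 0))
    stop("closure requires strictly positive entries; apply bm_replace() first")
  k * x / rowSums(x)
}

#' Centered log-ratio transform
#'
#' Maps each row (sample) of a strictly positive matrix to
#' \eqn{\log(x_j / g(x))} where \eqn{g(x)} is the geometric mean of the
#' row's parts.  The result lives in an unconstrained space where Euclidean
#' statistics (means, correlations) are meaningful; each transformed row sums
#' to zero, and the transform is invariant to closure and to any positive
#' rescaling of a row.
#'
#' @param x numeric matrix (or vector, treated as one sample) with strictly
#'   positive entries.
#' @return matrix of the same dimensions; rows sum to zero.
#' @examples
#' clr(matrix(c(1, exp(1)), 1, 2))   # -0.5, 0.5
#' @export
clr <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (any(x <= 0))
    stop("clr requires strictly positive entries")
  lx <- log(x)
  lx - rowMeans(lx)
}

#' Column-wise standardization
#'
#' Centers each column (feature) at its mean and scales it by its sample
#' standard deviation (denominator \eqn{n-1}).  The means and standard
#' deviations are attached as attributes `"center"` and `"scale"` for reuse
#' by the distortion machinery.
#'
#' @param x numeric matrix, samples in rows; at least two rows.
#' @return matrix with columns of mean 0 and sample standard deviation 1,
#'   with attributes `"center"` and `"scale"`.
#' @export
normalize_columns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop("normalization needs at least two samples")
  b <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad) > 0L) {
    ids <- colnames(x)[bad]
    if (is.null(ids)) ids <- as.character(bad)
    stop("zero-variance feature: ", paste(ids, collapse = ", "))
  }
  out <- sweep(sweep(x, 2L, b, "-"), 2L, s, "/")
  attr(out, "center") <- b
  attr(out, "scale") <- s
  out
}

#' Pretreatment pipeline for count tables
#'
#' Chains the compositional pretreatment stages: Bayesian-multiplicative
#' zero replacement, closure to constant `k`, centered log-ratio transform.
#' With `compositional = FALSE` (appropriate for data that are not
#' compositional, e.g. plain Gaussian measurements) the matrix is returned
#' as-is: log-ratio machinery must not be applied to non-compositional data.
#'
#' Note this returns data on the clr scale, not the standardized scale;
#' standardization is performed internally by [group_summary()] and
#' [correlation_matrix()].
#'
#' @param counts numeric matrix of non-negative counts (samples x features).
#' @param compositional logical; apply the compositional chain?
#' @param k closure constant passed to [closure()].
#' @return numeric matrix of pretreated values, same dimensions as `counts`.
#' @examples
#' pretreat(rbind(c(0, 2, 2), c(1, 1, 2)), compositional = TRUE)
#' @export
pretreat <- function(counts, compositional = TRUE, k = 100) {
  counts <- as.matrix(counts)
  if (!compositional) return(counts)
  clr(closure(bm_replace(counts), k = k))
}

# Validate and coerce a raw count table: non-negative, >= 2 features.
as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts))
    stop("count table must be numeric")
  if (ncol(counts) < 2L)
    stop("count table needs at least two features (clr is undefined for one part)")
  if (any(!is.finite(counts)))
    stop("count table contains non-finite entries")
  if (any(counts < 0))
    stop("count table contains negative entries")
  counts
}
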