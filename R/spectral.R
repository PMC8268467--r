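#' Pearson correlation matrix from standardized data
#'
#' Computes \eqn{S = X^T X / (n - 1)} where \eqn{X} is the column-standardized
#' data matrix, i.e. the ordinary Pearson correlation matrix of the features.
#'
#' @param x numeric matrix, samples in rows (at least two).  May already be
#'   standardized (output of [normalize_columns()]); if not, it is
#'   standardized internally.
#' @param normalized logical; set `TRUE` when `x` is already column-wise
#'   standardized to skip re-standardization.
#' @return symmetric matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, normalized = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop("correlation needs at least two samples")
  if (!normalized) x <- normalize_columns(x)
  s <- crossprod(x) / (nrow(x) - 1)
  (s + t(s)) / 2
}

#' Spectral decomposition with principal-component count selection
#'
#' Eigendecomposes a symmetric matrix (typically a correlation matrix),
#' orders eigenpairs by descending eigenvalue, canonicalizes eigenvector
#' signs (the entry of largest absolute value in each eigenvector is made
#' positive), and selects the number of leading components `a` needed to
#' explain at least a fraction \eqn{1 - \alpha} of the total variance
#' (the sum of all eigenvalues).
#'
#' @param s symmetric numeric matrix.
#' @param alpha fraction of total variance allowed to remain unexplained;
#'   `a` is the smallest count whose cumulative eigenvalue fraction reaches
#'   `1 - alpha`.
#' @return an object of class `"spectral_model"`: a list with elements
#'   `values` (eigenvalues, descending), `vectors` (orthonormal columns,
#'   sign-canonicalized), `n_components`, `alpha` and `m`.
#' @examples
#' spectral_decompose(generatrix(4, 0.3))
#' @export
spectral_decompose <- function(s, alpha = 0.05) {
  s <- as.matrix(s)
  if (nrow(s) != ncol(s) || max(abs(s - t(s))) > 1e-8)
    stop("matrix must be symmetric")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  v <- canonicalize_signs(e$vectors)
  a <- select_components(e$values, alpha)
  structure(list(values = e$values, vectors = v, n_components = a,
                 alpha = alpha, m = ncol(s)),
            class = "spectral_model")
}

# Flip eigenvector columns so the entry of largest |value| is positive.
canonicalize_signs <- function(v) {
  flip <- apply(v, 2L, function(col) col[which.max(abs(col))] < 0)
  v[, flip] <- -v[, flip, drop = FALSE]
  v
}

# Smallest a with cumulative eigenvalue fraction >= 1 - alpha.
select_components <- function(values, alpha) {
  frac <- cumsum(values) / sum(values)
  a <- which(frac >= (1 - alpha) - 1e-12)[1L]
  if (is.na(a)) a <- length(values)
  as.integer(a)
}

#' @export
print.spectral_model <- function(x, ...) {
  cat("Spectral model: ", x$m, " x ", x$m, " matrix, ",
      x$n_components, " component(s) explain >= ",
      100 * (1 - x$alpha), "% of total variance\n", sep = "")
  cat("Leading eigenvalues:",
      paste(signif(utils::head(x$values, 5L), 4), collapse = ", "),
      if (x$m > 5L) "..." else "", "\n")
  invisible(x)
}

#' Spectral distortion metric between two correlation structures
#'
#' Quantifies the distortion between a reference correlation structure and a
#' perturbed one as a weighted sum over leading eigenpairs of the eigenvalue
#' difference times the principal angle between the corresponding
#' eigenvectors:
#' \deqn{\varphi = \sum_{j=1}^{\max(a, \tilde a)}
#'   \max\{\lambda_j, \tilde\lambda_j\}\,
#'   (\lambda_j - \tilde\lambda_j)\,
#'   \arccos(|v_j^T \tilde v_j|)}
#' Eigenpairs are matched by descending-eigenvalue rank.  The inner product
#' is taken in absolute value before the arccosine because eigenvector signs
#' are arbitrary; the resulting angle lies in \eqn{[0, \pi/2]}.  The
#' \eqn{\max\{\lambda_j, \tilde\lambda_j\}} factor weights each term by the
#' importance of the component, so distortions of dominant components count
#' more.  \eqn{\varphi} can take either sign; it is zero when the two
#' structures share eigenvectors or eigenvalues termwise, and its magnitude
#' grows with the distortion.
#'
#' @param reference,distorted `"spectral_model"` objects over the same
#'   feature space (see [spectral_decompose()]).
#' @return a single numeric value.
#' @examples
#' m <- spectral_decompose(generatrix(5, 0.3))
#' phi_distortion(m, m)   # 0
#' @export
phi_distortion <- function(reference, distorted) {
  stopifnot(inherits(reference, "spectral_model"),
            inherits(distorted, "spectral_model"))
  if (reference$m != distorted$m)
    stop("models are over different feature spaces (",
         reference$m, " vs ", distorted$m, ")")
  jmax <- max(reference$n_components, distorted$n_components)
  lam <- reference$values[seq_len(jmax)]
  lam_t <- distorted$values[seq_len(jmax)]
  dots <- abs(colSums(reference$vectors[, seq_len(jmax), drop = FALSE] *
                      distorted$vectors[, seq_len(jmax), drop = FALSE]))
  angles <- acos(pmin(pmax(dots, 0), 1))
  sum(pmax(lam, lam_t) * (lam - lam_t) * angles)
}
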