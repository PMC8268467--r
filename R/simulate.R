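#' Equicorrelation generatrix matrix
#'
#' The compound-symmetry correlation matrix
#' \eqn{(1 - \rho) I_m + \rho \mathbf{1}\mathbf{1}^T}: unit diagonal,
#' constant off-diagonal \eqn{\rho}.  Positive definite for
#' \eqn{\rho \in (-1/(m-1), 1)}; its eigenvalues are \eqn{1 + (m-1)\rho}
#' (once) and \eqn{1 - \rho} (with multiplicity \eqn{m - 1}).
#'
#' @param m number of features (>= 2).
#' @param rho common correlation.
#' @return an `m` x `m` correlation matrix.
#' @examples
#' generatrix(3, 0.2)
#' @export
generatrix <- function(m, rho) {
  m <- as.integer(m)
  if (m < 2L) stop("`m` must be at least 2")
  if (!is.numeric(rho) || length(rho) != 1L ||
      rho <= -1 / (m - 1) || rho >= 1)
    stop("`rho` must lie in (-1/(m-1), 1) = (",
         signif(-1 / (m - 1), 4), ", 1) for positive definiteness")
  s <- matrix(rho, m, m)
  diag(s) <- 1
  s
}

#' Simulate a control/case pair of Gaussian sample matrices
#'
#' Draws two independent `n` x `m` matrices from zero-mean multivariate
#' Normal distributions whose covariance (= correlation) matrices are
#' equicorrelation generatrices with common correlations `rho_c` (control)
#' and `rho_v` (case).  This is the canonical synthetic benchmark for
#' correlation-structure classifiers: the two groups differ only in the
#' strength of a shared equicorrelation, not in any marginal mean or
#' variance.
#'
#' Sampling uses the Cholesky factor of the generatrix; results are
#' reproducible under [set.seed()] (or the `seed` argument).
#'
#' @param n samples per group.
#' @param m features.
#' @param rho_c,rho_v common correlation of the control / case generatrix.
#' @param seed optional integer; when supplied, [set.seed()] is called
#'   first so the draw is reproducible.
#' @return list with elements `control` and `case` (each `n` x `m`), plus
#'   the generating parameters as attributes.
#' @examples
#' sim <- simulate_groups(20, 5, 0.1, 0.2, seed = 1)
#' dim(sim$control)
#' @export
simulate_groups <- function(n, m, rho_c = 0.1, rho_v = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n < 4L) stop("`n` must be at least 4")
  out <- list(control = rmvn_equicorr(n, m, rho_c),
              case = rmvn_equicorr(n, m, rho_v))
  attr(out, "params") <- list(n = n, m = m, rho_c = rho_c, rho_v = rho_v)
  out
}

rmvn_equicorr <- function(n, m, rho) {
  ch <- chol(generatrix(m, rho))
  z <- matrix(stats::rnorm(n * m), n, m)
  x <- z %*% ch
  colnames(x) <- paste0("f", seq_len(m))
  rownames(x) <- paste0("s", seq_len(n))
  x
}
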