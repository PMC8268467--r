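# Shared fixtures, all generated in code.

# Random count matrix with a controllable fraction of zeros.
random_counts <- function(n, m, zero_frac = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(as.double(rpois(n * m, lambda = 20)), n, m)
  zeros <- sample(length(x), floor(zero_frac * length(x)))
  x[zeros] <- 0
  # guard: no all-zero rows
  for (i in which(rowSums(x) == 0)) x[i, 1] <- 1L
  dimnames(x) <- list(paste0("s", seq_len(n)), paste0("otu", seq_len(m)))
  x
}

# Random full-rank correlation matrix (non-degenerate spectrum w.h.p.).
random_correlation <- function(m, n = 5 * m) {
  stats::cov2cor(crossprod(matrix(rnorm(n * m), n, m)))
}

# Correlation-like symmetric matrices sharing an eigenbasis.
shared_basis_pair <- function(m, values1, values2) {
  v <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
  list(a = v %*% diag(values1) %*% t(v),
       b = v %*% diag(values2) %*% t(v))
}
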