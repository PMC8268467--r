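#' Sufficient statistics of a sample group
#'
#' Collects everything the distortion machinery needs from one group of
#' samples: the sample count, the feature means, the feature sample standard
#' deviations (denominator \eqn{n-1}) and the Pearson correlation matrix.
#'
#' @param x numeric matrix of (pretreated) values, samples in rows.
#' @return an object of class `"group_summary"`: list with elements `n`
#'   (samples), `m` (features), `mean`, `sd`, `correlation` and
#'   `feature_ids`.
#' @examples
#' g <- group_summary(matrix(rnorm(60), 20, 3))
#' g$correlation
#' @export
group_summary <- function(x) {
  x <- as.matrix(x)
  xn <- normalize_columns(x)
  structure(list(n = nrow(x), m = ncol(x),
                 mean = attr(xn, "center"),
                 sd = attr(xn, "scale"),
                 correlation = correlation_matrix(xn, normalized = TRUE),
                 feature_ids = colnames(x)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group summary: ", x$n, " samples, ", x$m, " features\n", sep = "")
  invisible(x)
}

#' Distorted mean vector after incorporating one sample
#'
#' The exact mean of a group augmented by one new sample is the convex
#' combination \eqn{\tilde b = \frac{n}{n+1} b + \frac{1}{n+1} x_p}.  Passing
#' an effective sample count `n_eff` smaller than the true group size
#' substitutes `n_eff` into these natural weights ("artificial dimensional
#' reduction"), increasing the influence of the new sample while the mean
#' `b` itself still summarizes the full group.
#'
#' @param summary a [group_summary()] object.
#' @param x_p numeric vector, the new sample (same features, same scale).
#' @param n_eff effective sample count (>= 2); defaults to the group size,
#'   which makes the result the exact augmented mean.
#' @return numeric vector of length `m`.
#' @export
distorted_mean <- function(summary, x_p, n_eff = summary$n) {
  check_distortion_args(summary, x_p, n_eff)
  (n_eff / (n_eff + 1)) * summary$mean + (1 / (n_eff + 1)) * x_p
}

#' Distorted standard deviations after incorporating one sample
#'
#' Per-feature update
#' \deqn{\tilde\sigma_i = \sqrt{\tfrac{n-1}{n}\sigma_i^2 + \Delta b_i^2
#'   + \tfrac{1}{n}(x_{p,i} - \tilde b_i)^2}}
#' with \eqn{\Delta b = \tilde b - b}.  At `n_eff` equal to the true group
#' size this is exactly the sample standard deviation (denominator
#' \eqn{n}) of the augmented data; smaller `n_eff` re-weights the new
#' sample's contribution.
#'
#' @inheritParams distorted_mean
#' @param b_tilde the distorted mean, as returned by [distorted_mean()]
#'   with the same `n_eff`; computed if missing.
#' @return numeric vector of strictly positive standard deviations.
#' @export
distorted_sd <- function(summary, x_p, b_tilde = NULL, n_eff = summary$n) {
  check_distortion_args(summary, x_p, n_eff)
  if (is.null(b_tilde)) b_tilde <- distorted_mean(summary, x_p, n_eff)
  if (length(b_tilde) != summary$m)
    stop("`b_tilde` has wrong length")
  db <- b_tilde - summary$mean
  sqrt(((n_eff - 1) / n_eff) * summary$sd^2 + db^2 +
         (1 / n_eff) * (x_p - b_tilde)^2)
}

#' Distorted correlation matrix after incorporating one sample
#'
#' Exact rank-one update of a group's Pearson correlation matrix when a new
#' sample is appended, written so that the group enters only through its
#' sufficient statistics:
#' \deqn{\tilde S = \tfrac{n-1}{n}\,\tilde\Sigma^{-1}\Sigma S \Sigma\tilde\Sigma^{-1}
#'   + \tilde\Sigma^{-1}\Delta b\,\Delta b^T \tilde\Sigma^{-1}
#'   + \tfrac{1}{n}\, x_{p,\mathrm{norm}}^T x_{p,\mathrm{norm}}}
#' where \eqn{\Sigma,\tilde\Sigma} are the diagonal matrices of original and
#' distorted standard deviations, \eqn{\Delta b} the mean shift and
#' \eqn{x_{p,\mathrm{norm}} = (x_p - \tilde b)\tilde\Sigma^{-1}}.  With
#' `n_eff` equal to the true group size the result is exactly the Pearson
#' correlation of the augmented matrix; with a reduced `n_eff` every
#' occurrence of the group size in the update weights is replaced by
#' `n_eff`, so the single new sample exerts the influence it would have in
#' a group of only `n_eff` samples, while `b`, `sd` and `S` still
#' summarize the full group.
#'
#' @inheritParams distorted_mean
#' @return an object of class `"distortion"`: list with elements `n_eff`,
#'   `b_tilde`, `sd_tilde`, `correlation` (the distorted matrix) and
#'   `x_p_norm`.
#' @examples
#' x <- matrix(rnorm(80), 20, 4)
#' xp <- rnorm(4)
#' d <- distorted_correlation(group_summary(x), xp)  # n_eff = 20: exact
#' max(abs(d$correlation - stats::cor(rbind(x, xp))))
#' @export
distorted_correlation <- function(summary, x_p, n_eff = summary$n) {
  check_distortion_args(summary, x_p, n_eff)
  b_tilde <- distorted_mean(summary, x_p, n_eff)
  sd_tilde <- distorted_sd(summary, x_p, b_tilde, n_eff)
  if (any(sd_tilde == 0))
    stop("distorted standard deviation is zero for some feature")
  db_n <- (b_tilde - summary$mean) / sd_tilde
  xp_n <- (x_p - b_tilde) / sd_tilde
  ratio <- summary$sd / sd_tilde
  s_tilde <- ((n_eff - 1) / n_eff) * (outer(ratio, ratio) * summary$correlation) +
    outer(db_n, db_n) + (1 / n_eff) * outer(xp_n, xp_n)
  s_tilde <- (s_tilde + t(s_tilde)) / 2
  structure(list(n_eff = n_eff, b_tilde = b_tilde, sd_tilde = sd_tilde,
                 correlation = s_tilde, x_p_norm = xp_n),
            class = "distortion")
}

#' Distortion profile over a sequence of artificial dimensions
#'
#' Evaluates the distortion metric \eqn{\varphi} between a group's
#' correlation structure and the structure distorted by a new sample, for
#' every effective sample count in the arithmetic sequence
#' `2, 2 + delta_n, ..., n_max`.  Small effective counts amplify the new
#' sample's influence; the full sequence traces how the distortion decays as
#' the artificial group size grows.
#'
#' @inheritParams distorted_mean
#' @param n_max largest effective sample count to evaluate; `n_max - 2`
#'   must be divisible by `delta_n`.
#' @param delta_n step of the sequence (positive integer).
#' @param alpha variance threshold passed to [spectral_decompose()].
#' @return a data frame with columns `n_red` and `phi`.
#' @export
distortion_profile <- function(summary, x_p, n_max = summary$n, delta_n = 1,
                               alpha = 0.05) {
  check_distortion_args(summary, x_p, 2L)
  delta_n <- as.integer(delta_n)
  n_max <- as.integer(n_max)
  if (delta_n < 1L) stop("`delta_n` must be a positive integer")
  if (n_max < 2L) stop("`n_max` must be at least 2")
  if ((n_max - 2L) %% delta_n != 0L)
    stop("n_max - 2 (= ", n_max - 2L, ") must be divisible by delta_n (= ",
         delta_n, "); reduce n_max to ",
         n_max - (n_max - 2L) %% delta_n, " or change delta_n")
  n_red <- seq.int(2L, n_max, by = delta_n)
  ref <- spectral_decompose(summary$correlation, alpha)
  phi <- vapply(n_red, function(ne) {
    d <- distorted_correlation(summary, x_p, ne)
    phi_distortion(ref, spectral_decompose(d$correlation, alpha))
  }, numeric(1))
  data.frame(n_red = n_red, phi = phi)
}

check_distortion_args <- function(summary, x_p, n_eff) {
  if (!inherits(summary, "group_summary"))
    stop("`summary` must be a group_summary object")
  if (length(x_p) != summary$m)
    stop("new sample has ", length(x_p), " features but the group has ",
         summary$m)
  if (!is.numeric(n_eff) || length(n_eff) != 1L || n_eff < 2)
    stop("`n_eff` must be a single integer >= 2")
  invisible(TRUE)
}
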