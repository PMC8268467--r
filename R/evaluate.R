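#' Classification accuracy on one control/case replicate
#'
#' Stacks the control and case matrices, classifies every row one-by-one
#' against the two fitted group summaries, and returns the percentage of
#' rows assigned to their source group, \eqn{100 N / (2n)}.  By default each
#' sample is classified against group statistics that include it
#' (resubstitution); `loo = TRUE` removes the sample from its own group
#' first, giving an honest error estimate.
#'
#' @param control,case numeric `n` x `m` matrices.
#' @param loo logical; leave-one-out scoring of the training rows.
#' @param ... settings passed to [phiclass()] (`alpha`, `delta_n`,
#'   `n_max`, `epsilon`, `compositional`, `k`).
#' @return accuracy in percent (a single number in \[0, 100\]).
#' @examples
#' sim <- simulate_groups(20, 10, 0.1, 0.5, seed = 1)
#' assess_replicate(sim$control, sim$case, delta_n = 2)
#' @export
assess_replicate <- function(control, case, loo = FALSE, ...) {
  fit <- phiclass(control, case, ...)
  total <- rbind(as.matrix(control), as.matrix(case))
  truth <- rep(c("control", "case"), c(nrow(control), nrow(case)))
  pred <- predict(fit, total, loo = loo)
  100 * mean(pred$predicted == truth)
}

#' Monte-Carlo accuracy over a grid of simulation configurations
#'
#' For each `(n, m)` configuration, simulates `B` independent control/case
#' replicate pairs from equicorrelation generatrices with common
#' correlations `rho_c` and `rho_v`, scores each replicate with
#' [assess_replicate()], and reports the mean accuracy with its Monte-Carlo
#' standard error.
#'
#' @param n,m equal-length integer vectors; configuration `i` uses
#'   `n[i]` samples per group and `m[i]` features.
#' @param rho_c,rho_v common correlations of the two generatrices.
#' @param B replicates per configuration.
#' @param seed optional integer; configuration `i`, replicate `r` uses seed
#'   `seed + 1000 * (i - 1) + r` so runs are reproducible and configurations
#'   independent.
#' @param loo leave-one-out scoring (see [assess_replicate()]).
#' @param verbose print a progress line per configuration.
#' @param ... classifier settings passed on to [phiclass()].
#' @return data frame with one row per configuration: `n`, `m`, `rho_c`,
#'   `rho_v`, `B`, `mean_accuracy`, `mc_stderr`; the per-replicate
#'   accuracies are attached as `attr(, "per_replicate")` (a list of
#'   numeric vectors).
#' @examples
#' accuracy_grid(n = 20, m = 10, rho_c = 0.1, rho_v = 0.5, B = 2,
#'               seed = 1, delta_n = 2)
#' @export
accuracy_grid <- function(n, m, rho_c = 0.1, rho_v = 0.2, B = 100,
                          seed = NULL, loo = FALSE, verbose = FALSE, ...) {
  if (length(n) != length(m))
    stop("`n` and `m` must have the same length (paired configurations)")
  per_rep <- vector("list", length(n))
  out <- data.frame(n = as.integer(n), m = as.integer(m),
                    rho_c = rho_c, rho_v = rho_v, B = as.integer(B),
                    mean_accuracy = NA_real_, mc_stderr = NA_real_)
  for (i in seq_along(n)) {
    acc <- vapply(seq_len(B), function(r) {
      sim <- simulate_groups(n[i], m[i], rho_c, rho_v,
                             seed = if (is.null(seed)) NULL
                                    else seed + 1000L * (i - 1L) + r)
      assess_replicate(sim$control, sim$case, loo = loo, ...)
    }, numeric(1))
    per_rep[[i]] <- acc
    out$mean_accuracy[i] <- mean(acc)
    out$mc_stderr[i] <- stats::sd(acc) / sqrt(B)
    if (verbose)
      message(sprintf("n = %d, m = %d: %.2f%% (+/- %.2f, B = %d)",
                      n[i], m[i], out$mean_accuracy[i], out$mc_stderr[i], B))
  }
  attr(out, "per_replicate") <- per_rep
  out
}
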