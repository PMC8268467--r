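#' Fit a correlation-structure distortion classifier
#'
#' Builds a two-group classifier from a control and a case sample matrix.
#' No parameters are estimated beyond the groups' sufficient statistics
#' (means, standard deviations, correlation matrices): a new sample is
#' assigned to the group whose correlation structure it distorts the least.
#' Distortion is measured by the spectral metric \eqn{\varphi}
#' ([phi_distortion()]) applied to the exact rank-one correlation update
#' ([distorted_correlation()]) evaluated over a ladder of artificial
#' effective sample counts `2, 2 + delta_n, ..., n_max`; affinity to a
#' group is the average inverse absolute distortion
#' \eqn{\bar\psi_g = \mathrm{mean}_{n_{red}}\, 1 / |\varphi|}.
#'
#' With `compositional = TRUE` both groups (and later any new samples) are
#' passed through the compositional pretreatment chain — Bayesian-
#' multiplicative zero replacement, closure, centered log-ratio — before any
#' statistic is computed.  Leave it `FALSE` for data that are not
#' compositional (e.g. Gaussian simulations), where log-ratio machinery does
#' not apply.
#'
#' @param control,case numeric matrices (samples x features) of raw counts
#'   (`compositional = TRUE`) or plain measurements, with matching feature
#'   columns.
#' @param compositional logical; apply the clr pretreatment chain.
#' @param alpha fraction of total variance left unexplained when selecting
#'   principal components for \eqn{\varphi} (default 0.05: the leading
#'   eigenpairs explaining 95 percent of variance are compared).
#' @param delta_n step of the artificial-dimension ladder.
#' @param n_max top of the ladder; `"auto"` uses the smaller group size,
#'   lowered if necessary so `n_max - 2` is divisible by `delta_n`.
#' @param epsilon guard for the reciprocal in the affinity score
#'   \eqn{\psi = 1/\max(|\varphi|, \epsilon)}.
#' @param k closure constant for compositional pretreatment.
#' @return an object of class `"phiclass"` with components `control` and
#'   `case` (each a [group_summary()] plus its spectral decomposition and
#'   the pretreated matrix), the resolved settings, and the `n_red`
#'   sequence.  Use [predict.phiclass()] to classify new samples.
#' @examples
#' set.seed(1)
#' sim <- simulate_groups(n = 30, m = 10, rho_c = 0.1, rho_v = 0.5)
#' fit <- phiclass(sim$control, sim$case)
#' predict(fit, sim$control[1:3, ])
#' @seealso [predict.phiclass()], [assess_replicate()], [simulate_groups()]
#' @export
phiclass <- function(control, case, compositional = FALSE, alpha = 0.05,
                     delta_n = 1, n_max = "auto", epsilon = 1e-12, k = 100) {
  control <- as.matrix(control)
  case <- as.matrix(case)
  if (ncol(control) != ncol(case))
    stop("control and case must have the same features (",
         ncol(control), " vs ", ncol(case), ")")
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("`epsilon` must be positive")
  xc <- pretreat(control, compositional = compositional, k = k)
  xv <- pretreat(case, compositional = compositional, k = k)
  delta_n <- as.integer(delta_n)
  if (delta_n < 1L) stop("`delta_n` must be a positive integer")
  n_max <- resolve_n_max(n_max, delta_n, nrow(xc), nrow(xv))
  fit <- structure(list(
    control = make_group(xc, alpha),
    case = make_group(xv, alpha),
    settings = list(compositional = compositional, alpha = alpha,
                    delta_n = delta_n, n_max = n_max, epsilon = epsilon,
                    k = k),
    n_red = seq.int(2L, n_max, by = delta_n),
    call = match.call()),
    class = "phiclass")
  fit
}

make_group <- function(x, alpha) {
  g <- group_summary(x)
  list(data = x, summary = g,
       spectral = spectral_decompose(g$correlation, alpha))
}

resolve_n_max <- function(n_max, delta_n, n_c, n_v) {
  lim <- min(n_c, n_v)
  if (identical(n_max, "auto")) {
    n_max <- lim - ((lim - 2L) %% delta_n)
  } else {
    n_max <- as.integer(n_max)
    if (n_max < 2L || n_max > lim)
      stop("`n_max` must lie in [2, min(n_c, n_v) = ", lim, "]")
    if ((n_max - 2L) %% delta_n != 0L)
      stop("n_max - 2 must be divisible by delta_n; nearest valid n_max is ",
           n_max - (n_max - 2L) %% delta_n)
  }
  as.integer(n_max)
}

#' Affinity score from a distortion value
#'
#' Inverse absolute distortion, \eqn{\psi = 1/\max(|\varphi|, \epsilon)}.
#' Large values indicate that the sample barely distorts the group's
#' correlation structure, i.e. high affinity with the group.
#'
#' @param phi numeric vector of distortion values.
#' @param epsilon positive guard against division by zero.
#' @return numeric vector of positive affinity scores.
#' @examples
#' psi_score(c(0.5, -0.25, 0))
#' @export
psi_score <- function(phi, epsilon = 1e-12) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("`epsilon` must be a single positive number")
  1 / pmax(abs(phi), epsilon)
}

#' Classify new samples with a fitted distortion classifier
#'
#' For each row of `newdata`, evaluates the distortion profile against both
#' groups over the fitted `n_red` ladder, converts distortions to affinity
#' scores \eqn{\psi = 1/|\varphi|}, averages them into \eqn{\bar\psi_c} and
#' \eqn{\bar\psi_v}, and predicts the group with the larger average.  Exact
#' ties go to the control group with a warning.
#'
#' @param object a fitted [phiclass()] model.
#' @param newdata numeric matrix (or vector for a single sample) of new
#'   samples on the same raw scale as the training matrices; pretreated
#'   automatically when the model is compositional.
#' @param loo logical; if `TRUE`, a row of `newdata` that exactly matches a
#'   training row is scored against its own group with that row removed
#'   (leave-one-out), giving an honest error estimate for training samples.
#' @param engine `"cpp"` (compiled fast path, default) or `"r"` (reference
#'   implementation via [distortion_profile()]); both give identical results.
#' @param ... unused.
#' @return an object of class `"phiclass_pred"`, a data frame with columns
#'   `sample_id`, `psi_bar_c`, `psi_bar_v`, `predicted`, with the
#'   per-dimension \eqn{\varphi}/\eqn{\psi} traces in
#'   `attr(, "traces")`.
#' @export
predict.phiclass <- function(object, newdata, loo = FALSE,
                             engine = c("cpp", "r"), ...) {
  engine <- match.arg(engine)
  st <- object$settings
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$control$summary$m)
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$control$summary$m)
  xp_all <- pretreat(newdata, compositional = st$compositional, k = st$k)
  ids <- rownames(newdata)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(nrow(newdata)))

  n_samples <- nrow(xp_all)
  psi_bar <- matrix(NA_real_, n_samples, 2L)
  traces <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    x_p <- xp_all[i, ]
    grp_c <- object$control
    grp_v <- object$case
    n_red <- object$n_red
    if (loo) {
      hit <- match_training_row(object, x_p)
      if (!is.na(hit["group"])) {
        grp <- if (hit["group"] == 1) grp_c else grp_v
        reduced <- make_group(grp$data[-hit["row"], , drop = FALSE], st$alpha)
        if (hit["group"] == 1) grp_c <- reduced else grp_v <- reduced
        lim <- min(grp_c$summary$n, grp_v$summary$n)
        top <- min(st$n_max, lim - ((lim - 2L) %% st$delta_n))
        n_red <- seq.int(2L, top, by = st$delta_n)
      }
    }
    phi_c <- group_phi_profile(grp_c, x_p, n_red, st$alpha, engine)
    phi_v <- group_phi_profile(grp_v, x_p, n_red, st$alpha, engine)
    psi_c <- psi_score(phi_c, st$epsilon)
    psi_v <- psi_score(phi_v, st$epsilon)
    psi_bar[i, ] <- c(mean(psi_c), mean(psi_v))
    traces[[i]] <- data.frame(n_red = n_red, phi_c = phi_c, phi_v = phi_v,
                              psi_c = psi_c, psi_v = psi_v)
  }
  ties <- psi_bar[, 1L] == psi_bar[, 2L]
  if (any(ties))
    warning("exact affinity tie for ", sum(ties),
            " sample(s); predicting control")
  out <- data.frame(sample_id = ids,
                    psi_bar_c = psi_bar[, 1L],
                    psi_bar_v = psi_bar[, 2L],
                    predicted = ifelse(psi_bar[, 2L] > psi_bar[, 1L],
                                       "case", "control"),
                    stringsAsFactors = FALSE)
  names(traces) <- ids
  attr(out, "traces") <- traces
  class(out) <- c("phiclass_pred", "data.frame")
  out
}

group_phi_profile <- function(group, x_p, n_red, alpha, engine = "cpp") {
  if (engine == "cpp") {
    g <- group$summary
    ref <- group$spectral
    .phi_profile_cpp(g$mean, g$sd, g$correlation, ref$values, ref$vectors,
                     ref$n_components, x_p, as.integer(n_red), alpha)
  } else {
    distortion_profile(group$summary, x_p, n_max = max(n_red),
                       delta_n = if (length(n_red) > 1L)
                         n_red[2L] - n_red[1L] else 1L,
                       alpha = alpha)$phi
  }
}

match_training_row <- function(object, x_p) {
  for (g in 1:2) {
    dat <- if (g == 1) object$control$data else object$case$data
    for (r in seq_len(nrow(dat))) {
      if (isTRUE(all.equal(unname(dat[r, ]), unname(x_p),
                           tolerance = 1e-12)))
        return(c(group = g, row = r))
    }
  }
  c(group = NA_integer_, row = NA_integer_)
}

#' @export
print.phiclass <- function(x, ...) {
  st <- x$settings
  cat("Correlation-structure distortion classifier\n\n")
  cat("  control: ", x$control$summary$n, " samples x ",
      x$control$summary$m, " features\n", sep = "")
  cat("  case:    ", x$case$summary$n, " samples x ",
      x$case$summary$m, " features\n", sep = "")
  cat("  compositional pretreatment:", st$compositional, "\n")
  cat("  alpha = ", st$alpha, ", n_red = 2, ",
      2 + st$delta_n, ", ..., ", st$n_max,
      "  (", length(x$n_red), " artificial dimensions)\n", sep = "")
  invisible(x)
}

#' @export
summary.phiclass <- function(object, ...) {
  out <- list(fit = object,
              components_c = object$control$spectral$n_components,
              components_v = object$case$spectral$n_components,
              top_eigen_c = utils::head(object$control$spectral$values, 5L),
              top_eigen_v = utils::head(object$case$spectral$values, 5L))
  class(out) <- "summary.phiclass"
  out
}

#' @export
print.summary.phiclass <- function(x, ...) {
  print(x$fit)
  cat("\n  principal components at alpha = ", x$fit$settings$alpha, ": ",
      x$components_c, " (control), ", x$components_v, " (case)\n", sep = "")
  cat("  leading eigenvalues (control):",
      paste(signif(x$top_eigen_c, 4), collapse = ", "), "\n")
  cat("  leading eigenvalues (case):   ",
      paste(signif(x$top_eigen_v, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Decision-plane coordinates and plot
#'
#' Plots each classified sample at \eqn{(\bar\psi_c, \bar\psi_v)} with the
#' identity line as the decision boundary: samples in the upper half-plane
#' are predicted case, samples below the line control.
#'
#' @param outcomes a `"phiclass_pred"` object (or data frame with columns
#'   `psi_bar_c`, `psi_bar_v`, `predicted`).
#' @param file optional path for an image (`.png` or `.svg` by extension);
#'   plotted to the active device when `NULL`.
#' @param table optional path for a TSV of the plotted coordinates.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, the coordinate data frame.
#' @export
decision_plane <- function(outcomes, file = NULL, table = NULL, ...) {
  if (nrow(outcomes) == 0L) stop("no outcomes to plot")
  coords <- as.data.frame(outcomes)[, c("sample_id", "psi_bar_c",
                                        "psi_bar_v", "predicted")]
  if (!is.null(table))
    utils::write.table(coords, table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 800, height = 800, res = 120),
           svg = grDevices::svg(file),
           stop("unsupported image format: ", ext))
    on.exit(grDevices::dev.off())
  }
  lim <- range(c(coords$psi_bar_c, coords$psi_bar_v))
  graphics::plot(coords$psi_bar_c, coords$psi_bar_v,
                 col = ifelse(coords$predicted == "case", "firebrick",
                              "steelblue"),
                 pch = 19, xlim = lim, ylim = lim,
                 xlab = expression(bar(psi)[c]),
                 ylab = expression(bar(psi)[v]), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("case", "control"), pch = 19,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(coords)
}

#' @rdname decision_plane
#' @param x a `"phiclass_pred"` object.
#' @export
plot.phiclass_pred <- function(x, ...) {
  decision_plane(x, ...)
}
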