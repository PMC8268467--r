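test_that("distorted_mean uses the natural weights, with the documented worked values", {
  g <- group_summary(matrix(rnorm(40), 10, 4))
  # weight arithmetic probed through b = 0, x_p = 1: b_tilde = w2
  g0 <- g; g0$mean <- rep(0, 4)
  ones <- rep(1, 4)
  expect_equal(distorted_mean(g0, ones, n_eff = 200), rep(1 / 201, 4),
               ignore_attr = TRUE)
  expect_equal(round(200 / 201, 3), 0.995)   # group weight at n = 200
  expect_equal(round(1 / 201, 3), 0.005)     # sample weight at n = 200
  expect_equal(distorted_mean(g0, ones, n_eff = 3), rep(0.25, 4),
               ignore_attr = TRUE)           # weights (0.75, 0.25) exactly

  # convex combination of equal points is a fixed point
  for (ne in c(2, 5, 50)) {
    expect_equal(distorted_mean(g, g$mean, n_eff = ne), g$mean)
  }
  expect_error(distorted_mean(g, rep(1, 3)), "features")
})

test_that("distorted_mean at full n equals the mean of the stacked matrix", {
  set.seed(31)
  x <- matrix(rnorm(60), 12, 5)
  xp <- rnorm(5)
  g <- group_summary(x)
  expect_equal(distorted_mean(g, xp), colMeans(rbind(x, xp)),
               ignore_attr = TRUE)
})

test_that("distorted_sd matches the stacked-matrix sd at full n and shrinks at the fixed point", {
  set.seed(32)
  x <- matrix(rnorm(80), 16, 5)
  xp <- rnorm(5)
  g <- group_summary(x)
  expect_equal(distorted_sd(g, xp), apply(rbind(x, xp), 2, sd),
               tolerance = 1e-12, ignore_attr = TRUE)
  # x_p at the group mean: only the first term survives
  for (ne in c(2, 7, 16)) {
    expect_equal(distorted_sd(g, g$mean, n_eff = ne),
                 g$sd * sqrt((ne - 1) / ne))
  }
  # monotone in the displacement of one coordinate
  base <- distorted_sd(g, g$mean, n_eff = 8)
  moved <- distorted_sd(g, g$mean + c(2, 0, 0, 0, 0), n_eff = 8)
  expect_gt(moved[1], base[1])
  expect_equal(moved[-1], base[-1])
})

test_that("distorted_correlation at full n reproduces the augmented Pearson matrix", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    m <- sample(2:20, 1)
    x <- matrix(rnorm(n * m), n, m)
    xp <- rnorm(m)
    d <- distorted_correlation(group_summary(x), xp)
    expect_lt(max(abs(d$correlation - cor(rbind(x, xp)))), 1e-8)
    expect_lt(max(abs(diag(d$correlation) - 1)), 1e-8)
  }
})

test_that("distorted_correlation stays symmetric for reduced n_eff and weights shift as expected", {
  set.seed(34)
  x <- matrix(rnorm(200), 20, 10)
  g <- group_summary(x)
  xp <- rnorm(10)
  for (ne in c(2, 3, 10, 20)) {
    d <- distorted_correlation(g, xp, n_eff = ne)
    expect_equal(d$correlation, t(d$correlation))
    expect_true(all(d$sd_tilde > 0))
  }
  # x_p at the group mean, full n: terms 2 and 3 vanish and the sign
  # pattern of the correlation is preserved
  d0 <- distorted_correlation(g, g$mean)
  expect_equal(d0$x_p_norm, rep(0, 10), ignore_attr = TRUE)
  off <- upper.tri(d0$correlation)
  expect_equal(sign(d0$correlation[off]), sign(g$correlation[off]))
})

test_that("distortion_profile follows the n_red ladder contract", {
  set.seed(35)
  g <- group_summary(matrix(rnorm(150), 15, 10))
  xp <- rnorm(10)
  prof <- distortion_profile(g, xp, n_max = 10, delta_n = 2)
  expect_equal(prof$n_red, c(2, 4, 6, 8, 10))
  expect_equal(nrow(prof), (10 - 2) / 2 + 1)
  expect_true(all(is.finite(prof$phi)))

  single <- distortion_profile(g, xp, n_max = 2, delta_n = 5)
  expect_equal(single$n_red, 2)
  expect_equal(nrow(single), 1L)

  expect_error(distortion_profile(g, xp, n_max = 7, delta_n = 2),
               "divisible")
})

test_that("in-distribution samples distort less than foreign ones at full dimension", {
  set.seed(36)
  sim <- simulate_groups(30, 8, rho_c = 0.1, rho_v = 0.8)
  g <- group_summary(sim$control)
  ref <- spectral_decompose(g$correlation)
  phi_of <- function(xp) {
    abs(phi_distortion(ref,
        spectral_decompose(distorted_correlation(g, xp)$correlation)))
  }
  own <- apply(sim$control, 1, phi_of)      # rows already inside the summary
  foreign <- apply(sim$case, 1, phi_of)
  expect_lt(median(own), median(foreign))
})
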