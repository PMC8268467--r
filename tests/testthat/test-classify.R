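test_that("psi_score is the guarded reciprocal of |phi|", {
  expect_equal(psi_score(0.5), 2.0)
  expect_equal(psi_score(-0.25), 4.0)
  expect_equal(psi_score(0), 1e12)
  expect_equal(psi_score(0, epsilon = 1e-6), 1e6)
  expect_error(psi_score(1, epsilon = 0), "positive")
})

test_that("the fitted object resolves settings and ladders correctly", {
  set.seed(41)
  sim <- simulate_groups(21, 6, 0.1, 0.5)
  fit <- phiclass(sim$control, sim$case, delta_n = 2)
  expect_s3_class(fit, "phiclass")
  expect_equal(fit$settings$n_max, 20)          # 21 lowered for divisibility
  expect_equal(fit$n_red, seq(2, 20, by = 2))
  expect_error(phiclass(sim$control, sim$case, n_max = 7, delta_n = 2),
               "divisible")
  expect_error(phiclass(sim$control, sim$case[, 1:5]), "same features")
  expect_output(print(fit), "artificial dimensions")
  expect_output(print(summary(fit)), "principal components")
})

test_that("compiled and reference profile engines agree", {
  set.seed(42)
  sim <- simulate_groups(15, 8, 0.1, 0.4)
  fit <- phiclass(sim$control, sim$case, delta_n = 1)
  x <- rbind(sim$control[1:2, ], sim$case[1:2, ])
  p_cpp <- predict(fit, x, engine = "cpp")
  p_r <- predict(fit, x, engine = "r")
  expect_equal(p_cpp$psi_bar_c, p_r$psi_bar_c, tolerance = 1e-6)
  expect_equal(p_cpp$psi_bar_v, p_r$psi_bar_v, tolerance = 1e-6)
  expect_identical(p_cpp$predicted, p_r$predicted)
})

test_that("swapping control and case swaps scores and flips predictions", {
  set.seed(43)
  sim <- simulate_groups(20, 8, 0.1, 0.6)
  fit <- phiclass(sim$control, sim$case)
  tif <- phiclass(sim$case, sim$control)
  x <- rbind(sim$control[1:3, ], sim$case[1:3, ])
  p1 <- predict(fit, x)
  p2 <- predict(tif, x)
  expect_equal(p1$psi_bar_c, p2$psi_bar_v, tolerance = 1e-10)
  expect_equal(p1$psi_bar_v, p2$psi_bar_c, tolerance = 1e-10)
  expect_identical(p1$predicted == "control", p2$predicted == "case")
})

test_that("scores are invariant to the row order of the group matrices", {
  set.seed(44)
  sim <- simulate_groups(18, 6, 0.1, 0.5)
  x <- rnorm(6)
  p1 <- predict(phiclass(sim$control, sim$case), x)
  p2 <- predict(phiclass(sim$control[sample(18), ], sim$case[sample(18), ]), x)
  expect_equal(p1$psi_bar_c, p2$psi_bar_c, tolerance = 1e-9)
  expect_equal(p1$psi_bar_v, p2$psi_bar_v, tolerance = 1e-9)
})

test_that("identical groups tie exactly and the tie goes to control with a warning", {
  set.seed(45)
  x <- matrix(rnorm(120), 20, 6)
  fit <- phiclass(x, x)
  expect_warning(p <- predict(fit, rnorm(6)), "tie")
  expect_identical(p$predicted, "control")
  expect_equal(p$psi_bar_c, p$psi_bar_v)
})

test_that("resubstituted training rows lean toward their own group under strong separation", {
  set.seed(46)
  sim <- simulate_groups(40, 10, rho_c = 0.1, rho_v = 0.9)
  fit <- phiclass(sim$control, sim$case)
  p <- predict(fit, sim$control)
  expect_gt(mean(p$predicted == "control"), 0.5)
})

test_that("leave-one-out rebuilds the group without the matched row", {
  set.seed(47)
  sim <- simulate_groups(12, 5, 0.1, 0.5)
  fit <- phiclass(sim$control, sim$case)
  x <- sim$control[3, ]
  p_in <- predict(fit, x)
  p_out <- predict(fit, x, loo = TRUE)
  # the loo score against control must equal scoring against the group
  # refit without that row
  fit_wo <- phiclass(sim$control[-3, ], sim$case,
                     n_max = min(11, fit$settings$n_max))
  p_ref <- predict(fit_wo, x)
  expect_equal(p_out$psi_bar_c, p_ref$psi_bar_c, tolerance = 1e-9)
  # and generally differ from the resubstitution score
  expect_false(isTRUE(all.equal(p_in$psi_bar_c, p_out$psi_bar_c)))
})

test_that("stronger correlation contrast does not reduce accuracy", {
  set.seed(48)
  B <- 8
  acc <- sapply(c(0.2, 0.5), function(rv) {
    mean(sapply(seq_len(B), function(r) {
      sim <- simulate_groups(40, 20, 0.1, rv, seed = 4800 + r)
      assess_replicate(sim$control, sim$case, delta_n = 2)
    }))
  })
  expect_gte(acc[2], acc[1] - 5)  # within Monte-Carlo error
})

test_that("decision_plane writes coordinates that round-trip the outcomes", {
  set.seed(49)
  sim <- simulate_groups(15, 6, 0.1, 0.5)
  fit <- phiclass(sim$control, sim$case)
  p <- predict(fit, rbind(sim$control[1:2, ], sim$case[1:2, ]))
  tsv <- tempfile(fileext = ".tsv")
  png <- tempfile(fileext = ".png")
  coords <- decision_plane(p, file = png, table = tsv)
  expect_true(file.exists(png))
  back <- read.delim(tsv)
  expect_equal(back$psi_bar_c, p$psi_bar_c)
  expect_equal(back$psi_bar_v, p$psi_bar_v)
  expect_equal(back$predicted, p$predicted)
  # points above the identity line are exactly the case-predicted ones
  expect_identical(coords$psi_bar_v > coords$psi_bar_c,
                   coords$predicted == "case")
  unlink(c(tsv, png))
})
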