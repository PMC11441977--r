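test_that("noiseless law-generated points recover slope and intercept exactly", {
  d <- law_points(n = 10, k = 0.2277, alpha = 1.25)
  f <- fit_scaling_law(d)
  expect_lt(abs(f$alpha - 1.25), 1e-9)
  expect_lt(abs(f$log_k - log10(0.2277)), 1e-9)
  expect_equal(f$df, 2 * f$alpha)
  expect_gt(f$r2, 1 - 1e-12)
  expect_equal(f$k, 0.2277, tolerance = 1e-9)
})

test_that("convex points with constant thickness give slope exactly 1", {
  Ae <- 10^seq(3, 5, length.out = 8)
  d <- data.frame(At = Ae, Ae = Ae, T = 2, native = FALSE, lambda = 1:8)
  f <- fit_scaling_law(d)
  expect_lt(abs(f$alpha - 1), 1e-12)
})

test_that("degenerate inputs are rejected", {
  d <- law_points(n = 2)
  expect_error(fit_scaling_law(d), "at least 3")
  d3 <- data.frame(At = c(1, 2, 3) * 100, Ae = rep(100, 3), T = 1,
                   native = FALSE, lambda = 1:3)
  expect_error(fit_scaling_law(d3), "zero variance")
})

test_that("alpha is unbiased under multiplicative log-normal noise", {
  alphas <- vapply(1:200, function(s) {
    d <- law_points(n = 12, sigma = 0.01, seed = s)
    fit_scaling_law(d)$alpha
  }, 0)
  mc_se <- stats::sd(alphas) / sqrt(length(alphas))
  expect_lt(abs(mean(alphas) - 1.25), 3 * mc_se + 1e-4)
})

test_that("group fits pool objects and recover the intercept spread", {
  trajs <- replicate(5, law_points(n = 8), simplify = FALSE)
  g <- fit_group_slope(trajs)
  expect_equal(g$slope, 1.25, tolerance = 1e-9)
  expect_equal(g$intercept_sd, 0, tolerance = 1e-12)
  # intercepts drawn N(-0.64, 0.02^2): recovered sd within 50% at n = 20
  trajs2 <- cortexscale:::with_seed(42, lapply(1:20, function(i)
    law_points(n = 8, k = 10^rnorm(1, -0.64, 0.02))))
  g2 <- fit_group_slope(trajs2)
  expect_gt(g2$intercept_sd, 0.01)
  expect_lt(g2$intercept_sd, 0.03)
  expect_equal(g2$intercept_mean, -0.64, tolerance = 0.02)
  # lmm route reports the same fields
  if (requireNamespace("lme4", quietly = TRUE)) {
    g3 <- fit_group_slope(trajs2, method = "lmm")
    expect_equal(g3$slope, 1.25, tolerance = 1e-6)
    expect_gt(g3$intercept_sd, 0.005)
    expect_lt(g3$intercept_sd, 0.04)
  }
  # unfittable member is named
  bad <- c(trajs, list(law_points(n = 2)))
  expect_error(fit_group_slope(bad), "trajectory 6 unfittable")
})

test_that("box counting: solid cube slope 3, thin slab slope 2", {
  bc <- box_count_dimension(make_cube(8), c(1, 2, 4))
  expect_equal(bc$counts$N, c(512, 64, 8))
  expect_lt(abs(bc$df - 3), 1e-9)
  bs <- box_count_dimension(make_slab(16, 16, 0.25), c(1, 2, 4))
  expect_equal(bs$counts$N, c(256, 64, 16))
  expect_lt(abs(bs$df - 2), 1e-9)
  expect_error(box_count_dimension(make_cube(8), c(2)), "at least 3")
})

test_that("fundamental area element and feature counts", {
  expect_equal(compute_A0(1, 1), 1)
  a0 <- compute_A0(2.5, 0.2277)
  expect_equal(a0, 6.25 / 0.2277^4, tolerance = 1e-12)
  expect_equal(a0, 2325, tolerance = 1e-3)
  expect_equal(feature_count(1e5, a0), 43.0, tolerance = 1e-2)
  expect_error(compute_A0(-1, 1), "positive")
})

test_that("trajectory classification labels convex, flat-fractal and other", {
  slab <- make_slab(20, 20, 1)
  traj <- measure_sweep(slab, scales = c(0.4, 0.6, 0.9, 1.35, 2, 3),
                        mode = "faces")
  cl <- classify_trajectory(traj)
  expect_equal(cl$label, "convex-line")
  expect_lt(abs(cl$slope - (-1 / 9)), 0.02)

  flat <- fixture_traj(K = rep(-0.6, 5) + rnorm(5, 0, 1e-4),
                       S = seq(9, 5, length.out = 5))
  expect_equal(classify_trajectory(flat)$label, "flat-fractal")

  scatter <- cortexscale:::with_seed(7,
    fixture_traj(K = rnorm(8), S = rnorm(8)))
  expect_equal(classify_trajectory(scatter)$label, "other")
  expect_error(classify_trajectory(flat[1:2, ]), "at least 3")
})
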