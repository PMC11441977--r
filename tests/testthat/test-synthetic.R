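test_that("convex generators match closed forms and reject bad dimensions", {
  slab <- make_slab(20, 20, 1)
  expect_equal(mesh_area(slab), 880)
  expect_error(make_slab(0, 1, 1), "positive")
  shell <- make_sphere_shell(10, 2, 5)
  expect_lt(abs(mesh_area(shell$pial) / (400 * pi) - 1), 0.005)
  expect_lt(abs(mesh_area(shell$white) / (4 * pi * 64) - 1), 0.005)
  expect_error(make_sphere_shell(10, 12), "0 < t < r")
  expect_error(make_sphere_shell(10, 10), "0 < t < r")
})

test_that("all generated pairs pass validation", {
  shapes <- list(
    make_sphere_shell(8, 2, 3),
    make_sinusoid_shell(8, data.frame(frequency = 10, amplitude = 0.7),
                        t = 1, subdiv = 4, seed = 1),
    make_fbm_shell(10, H = 0.5, amplitude = 2, t = 1, subdiv = 4, seed = 1)
  )
  for (p in shapes) expect_true(validate_pair(p)$ok)
})

test_that("empty fold spectrum recovers the plain sphere shell", {
  a <- make_sinusoid_shell(9, folds = NULL, t = 2, subdiv = 4)
  b <- make_sphere_shell(9, 2, 4)
  expect_lt(abs(mesh_area(a$pial) / mesh_area(b$pial) - 1), 1e-3)
  expect_lt(abs(mesh_area(a$white) / mesh_area(b$white) - 1), 1e-3)
})

test_that("sinusoid shells: seeded determinism and displacement guard", {
  folds <- data.frame(frequency = 12, amplitude = 0.8)
  a <- make_sinusoid_shell(8, folds, t = 1, subdiv = 3, seed = 4)
  b <- make_sinusoid_shell(8, folds, t = 1, subdiv = 3, seed = 4)
  expect_identical(a$pial$vertices, b$pial$vertices)
  c <- make_sinusoid_shell(8, folds, t = 1, subdiv = 3, seed = 5)
  expect_false(identical(a$pial$vertices, c$pial$vertices))
  expect_error(make_sinusoid_shell(8, folds, t = 1, subdiv = 3),
               "require a seed")
  expect_error(make_sinusoid_shell(
    8, data.frame(frequency = 12, amplitude = 5), t = 1, subdiv = 3, seed = 4),
    "exceeds R/2")
})

test_that("fbm shells: determinism, H domain, band guard", {
  a <- make_fbm_shell(10, 0.5, amplitude = 2, t = 1, subdiv = 4, seed = 9)
  b <- make_fbm_shell(10, 0.5, amplitude = 2, t = 1, subdiv = 4, seed = 9)
  expect_identical(a$pial$vertices, b$pial$vertices)
  expect_error(make_fbm_shell(10, 1.2, seed = 1), "H must be")
  expect_error(make_fbm_shell(10, 0.5, subdiv = 4, seed = 1,
                              band = c(5, 4)), "band")
  expect_error(make_fbm_shell(10, 0.5, subdiv = 3), "seed")
})

test_that("single-frequency folds erase above the wavelength, persist below", {
  R <- 20; f <- 30; w <- 2 * pi * R / f
  pair <- make_sinusoid_shell(R, data.frame(frequency = f, amplitude = 2),
                              t = 1, subdiv = 6, seed = 11)
  nat_exc <- mesh_area(pair$pial) - convex_hull_area(pair$pial)
  traj <- measure_sweep(pair, scales = c(w / 4, 1.5 * w, 2 * w),
                        mode = "marching", smooth_iters = 10)
  retained <- (traj$At_raw - traj$Ae_raw) / nat_exc
  expect_gt(retained[1], 0.9)       # lambda = w/4: folds still present
  expect_lt(retained[2], 0.10)      # lambda > w: folds melted away
  expect_lt(retained[3], 0.10)
})

test_that("cohorts: structure, band deltas, errors", {
  base <- list(R = 6, t = 1, subdiv = 3,
               folds = data.frame(frequency = c(8, 14),
                                  amplitude = c(0.4, 0.3)))
  coh <- make_cohort(2, base, band_delta = list(frequency = 14, delta = 0.2),
                     seed = 1)
  expect_length(coh, 4)
  expect_equal(vapply(coh, `[[`, "", "group"), c("A", "A", "B", "B"))
  for (s in coh) expect_true(validate_pair(s$pair)$ok)
  expect_error(make_cohort(1, base, seed = 1), "at least 2")
  expect_error(make_cohort(2, base,
                           band_delta = list(frequency = 99, delta = 0.1),
                           seed = 1), "does not match")
  expect_error(make_cohort(2, base,
                           band_delta = list(frequency = 14, delta = -5),
                           seed = 1), "negative")
})
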