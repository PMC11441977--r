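test_that("coarse measurements match closed forms for voxel solids", {
  # solid cube, faces mode: At = Ae = 6 a^2, T = a/3
  cube <- make_cube(6)
  g <- voxelise_ribbon(cube, 1)
  s <- extract_surfaces(g, "faces")
  r <- measure_realisation(s, g)
  expect_equal(r$At, 216)
  expect_equal(r$Ae, 216, tolerance = 1e-9)
  expect_equal(r$V, 216)
  expect_equal(r$T, 2, tolerance = 1e-9)   # a/3 = 2

  # hollow block: V = 26, At = 54, Ai = 6 -> T = 52/60
  occ <- array(FALSE, c(5, 5, 5))
  occ[2:4, 2:4, 2:4] <- TRUE
  occ[3, 3, 3] <- FALSE
  gh <- cortexscale:::new_grid(c(0, 0, 0), 1, occ)
  rh <- measure_realisation(extract_surfaces(gh, "faces"), gh)
  expect_equal(rh$V, 26)
  expect_equal(rh$At, 54)
  expect_equal(rh$Ai, 6)
  expect_equal(rh$T, 52 / 60, tolerance = 1e-12)
})

test_that("slab thickness is recovered within 5% for lambda <= t/2", {
  slab <- make_slab(100, 100, 1)
  for (lam in c(0.25, 0.5)) {
    g <- voxelise_ribbon(slab, lam)
    r <- measure_realisation(extract_surfaces(g, "faces"), g)
    expect_lt(abs(r$T - 1), 0.05, label = sprintf("T at lambda=%g", lam))
  }
})

test_that("native measurement: concentric shells, isometry, single-surface error", {
  pair <- make_sphere_shell(10, 2, 4)
  nat <- measure_native(pair)
  expect_lt(abs(nat$T - 2), 2e-3)
  expect_equal(nat$At, mesh_area(pair$pial))
  expect_equal(nat$Ae, mesh_area(pair$pial), tolerance = 1e-9) # convex
  expect_equal(nat$V,
               mesh_volume(pair$pial) - mesh_volume(pair$white))
  # isometric scaling: areas x4, thickness x2
  pair2 <- surface_pair(scale_mesh(pair$pial, 2), scale_mesh(pair$white, 2))
  nat2 <- measure_native(pair2)
  expect_equal(nat2$At / nat$At, 4, tolerance = 1e-12)
  expect_equal(nat2$Ae / nat$Ae, 4, tolerance = 1e-9)
  expect_equal(nat2$T / nat$T, 2, tolerance = 1e-12)
  expect_error(measure_native(surface_pair(pair$pial)), "white surface")
})

test_that("isometric rescaling scales measures and leaves K and S fixed", {
  r <- cortexscale:::new_realisation(lambda = 2, At = 500, Ae = 300, Ai = 100,
                                     T = 1.7, V = 120, N = 15, mode = "faces")
  # identity at lambda_ref = lambda
  expect_equal(rescale_realisation(r, 2)$At, r$At)
  # s = 0.5: areas x 0.25, T x 0.5, V x 0.125
  r2 <- rescale_realisation(r, 1)
  expect_equal(r2$At, r$At * 0.25)
  expect_equal(r2$Ae, r$Ae * 0.25)
  expect_equal(r2$T, r$T * 0.5)
  expect_equal(r2$V, r$V * 0.125)
  k0 <- kis_coordinates(r$At, r$Ae, r$T)
  k1 <- kis_coordinates(r2$At, r2$Ae, r2$T)
  expect_lt(abs(k0$K - k1$K), 1e-12)
  expect_lt(abs(k0$S - k1$S), 1e-12)
  expect_error(rescale_realisation(r, -1), "positive")
  expect_error(rescale_realisation(r2, 1), "already rescaled")
})

test_that("K/I/S closed forms, isometric shifts and orthogonality", {
  # convex case At = Ae = 1e4, T = 1
  k <- kis_coordinates(1e4, 1e4, 1)
  expect_equal(k$K, -1, tolerance = 1e-12)
  expect_equal(k$S, 9, tolerance = 1e-12)
  expect_equal(k$I, 8, tolerance = 1e-12)
  expect_equal(k$K, -k$S / 9, tolerance = 1e-12)
  # isometric x10: K, S unchanged, I shifts by 6 log10(10)
  k10 <- kis_coordinates(1e6, 1e6, 10)
  expect_equal(k10$K, k$K, tolerance = 1e-12)
  expect_equal(k10$S, k$S, tolerance = 1e-12)
  expect_equal(k10$I, 14, tolerance = 1e-12)
  # independent spreadsheet-style evaluation of the three linear forms
  At <- 1e5; Ae <- 1e4; T <- 2.5
  lT2 <- log10(T^2)
  expect_equal(kis_coordinates(At, Ae, T)$K, 5 - 1.25 * 4 + 0.25 * lT2,
               tolerance = 1e-12)
  expect_equal(kis_coordinates(At, Ae, T)$I, 5 + 4 + lT2, tolerance = 1e-12)
  expect_equal(kis_coordinates(At, Ae, T)$S, 7.5 + 3 - 2.25 * lT2,
               tolerance = 1e-12)
  expect_error(kis_coordinates(-1, 1, 1), "positive")
  # coefficient vectors exactly orthogonal; stated normalisation constants
  B <- kis_basis()
  G <- B %*% t(B)
  expect_identical(G[upper.tri(G)], rep(0, 3))
  expect_equal(sqrt(diag(G)), c(K = sqrt(42) / 4, I = sqrt(3),
                                S = sqrt(126) / 4), tolerance = 1e-15)
  Bn <- kis_basis(normalised = TRUE)
  expect_equal(unname(rowSums(Bn^2)), rep(1, 3), tolerance = 1e-15)
})

test_that("trajectories: hull bound and thickness bounded by native + lambda_ref", {
  pair <- make_sinusoid_shell(8, data.frame(frequency = 10, amplitude = 0.8),
                              t = 1.5, subdiv = 4, seed = 2)
  lam_ref <- 0.6
  traj <- measure_sweep(pair, scales = c(0.6, 1, 1.8, 3.2),
                        mode = "marching", smooth_iters = 10,
                        native = TRUE, pair = pair, lambda_ref = lam_ref)
  expect_true(all(traj$Ae <= traj$At + 1e-9 * traj$At))
  T_native <- traj$T[traj$native]
  # conservative occupancy thickens the ribbon by at most ~half a box per
  # side; after rescaling that is bounded by sqrt(3) * lambda_ref
  expect_true(all(traj$T[!traj$native] <= T_native + sqrt(3) * lam_ref))
  expect_true(all(diff(traj$lambda) > 0))
  expect_true(all(c("K", "I", "S", "At_raw") %in% names(traj)))
})
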