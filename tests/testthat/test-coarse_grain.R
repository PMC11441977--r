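test_that("voxelisation counts are exact for axis-aligned solids", {
  slab <- make_slab(20, 20, 1)
  g <- voxelise_ribbon(slab, 1)
  expect_equal(g$n_occupied, 400)
  cube <- make_cube(8)
  expect_equal(voxelise_ribbon(cube, 2)$n_occupied, 64)
  expect_equal(voxelise_ribbon(cube, 1)$n_occupied, 512)
})

test_that("invalid scales are rejected with informative errors", {
  slab <- make_slab(20, 20, 1)
  expect_error(voxelise_ribbon(slab, 0), "positive")
  expect_error(voxelise_ribbon(slab, -1), "positive")
  expect_error(voxelise_ribbon(slab, 25), "maximum usable lambda")
})

test_that("occupancy equals the brute-force per-voxel oracle on all fixtures", {
  fixtures <- list(
    slab = list(obj = make_slab(10, 10, 1), lambda = 1),
    cube = list(obj = make_cube(6), lambda = 0.8),
    sphere_shell = list(obj = make_sphere_shell(5, 1.5, 3), lambda = 0.55),
    sinusoid_shell = list(
      obj = make_sinusoid_shell(5, data.frame(frequency = 8, amplitude = 0.5),
                                t = 1, subdiv = 3, seed = 5),
      lambda = 0.6)
  )
  for (nm in names(fixtures)) {
    fx <- fixtures[[nm]]
    g <- voxelise_ribbon(fx$obj, fx$lambda)
    expect_lte(max(dim(g$occupancy)), 32)
    oracle <- oracle_occupancy(fx$obj, g$origin, g$spacing, dim(g$occupancy))
    expect_identical(g$occupancy, oracle, label = paste("occupancy", nm))
  }
  # and once on a jittered (non-aligned) grid
  g <- voxelise_ribbon(fixtures$sphere_shell$obj, 0.55,
                       origin_policy = "jitter", seed = 3)
  oracle <- oracle_occupancy(fixtures$sphere_shell$obj, g$origin, g$spacing,
                             dim(g$occupancy))
  expect_identical(g$occupancy, oracle)
})

test_that("faces-mode surfaces have exact voxel-face areas and cavities", {
  occ <- array(FALSE, c(3, 3, 3)); occ[2, 2, 2] <- TRUE
  g1 <- cortexscale:::new_grid(c(0, 0, 0), 1.5, occ)
  s1 <- extract_surfaces(g1, "faces")
  expect_equal(mesh_area(s1$outer), 6 * 1.5^2)
  expect_null(s1$inner)
  expect_true(mesh_edge_report(s1$outer)$watertight)

  # 3x3x3 block with the centre removed: outer 54, inner cavity 6
  occ <- array(FALSE, c(5, 5, 5))
  occ[2:4, 2:4, 2:4] <- TRUE
  occ[3, 3, 3] <- FALSE
  g2 <- cortexscale:::new_grid(c(0, 0, 0), 1, occ)
  s2 <- extract_surfaces(g2, "faces")
  expect_equal(mesh_area(s2$outer), 54)
  expect_equal(mesh_area(s2$inner), 6)
  expect_true(mesh_edge_report(s2$inner)$watertight)
  expect_error(extract_surfaces(cortexscale:::new_grid(c(0, 0, 0), 1,
                                                       array(FALSE, c(2, 2, 2)))),
               "empty")
})

test_that("marching-mode surfaces are watertight with bounded area bias", {
  sp <- icosphere(4, 10)
  g <- voxelise_ribbon(sp, 0.25)   # lambda = r/40
  s <- extract_surfaces(g, "marching", smooth_iters = 40)
  expect_true(mesh_edge_report(s$outer)$watertight)
  # hull of the iso-surface tracks the analytic sphere closely; the
  # iso-surface area keeps a small positive staircase bias (documented)
  expect_lt(abs(convex_hull_area(s$outer) / (4 * pi * 100) - 1), 0.07)
  bias <- mesh_area(s$outer) / (4 * pi * 100) - 1
  expect_gt(bias, 0)
  expect_lt(bias, 0.12)
  # volume-preserving smoothing contract
  raw <- extract_surfaces(g, "marching", smooth_iters = 0)
  expect_lt(abs(mesh_volume(s$outer) / mesh_volume(raw$outer) - 1), 0.04)
})

test_that("nested grids are monotone: N(2*lambda) <= N(lambda), voxelwise", {
  for (obj in list(make_slab(12, 12, 1.3),
                   make_sphere_shell(6, 2, 3),
                   make_sinusoid_shell(5, data.frame(frequency = 8,
                                                     amplitude = 0.5),
                                       t = 1, subdiv = 3, seed = 5))) {
    lam <- 0.5
    g1 <- voxelise_ribbon(obj, lam)
    g2 <- voxelise_ribbon(obj, 2 * lam)
    expect_lte(g2$n_occupied, g1$n_occupied)
    # every occupied coarse voxel contains at least one occupied fine voxel
    idx2 <- which(g2$occupancy, arr.ind = TRUE)
    d1 <- dim(g1$occupancy)
    ok <- apply(idx2, 1, function(v) {
      lo <- g2$origin + (v - 1) * 2 * lam
      i0 <- round((lo - g1$origin) / lam) + 1
      any(g1$occupancy[
        max(1, i0[1]):min(d1[1], i0[1] + 1),
        max(1, i0[2]):min(d1[2], i0[2] + 1),
        max(1, i0[3]):min(d1[3], i0[3] + 1)])
    })
    expect_true(all(ok))
  }
})

test_that("two ridges stay separate below half the gap and fuse above twice it", {
  g <- 2
  ridges <- fixture_two_ridges(g = g, side = 8, thick = 1)
  fine <- voxelise_ribbon(ridges, g / 2 - 0.1)
  expect_equal(grid_components(fine, 26), 2)
  coarse <- voxelise_ribbon(ridges, 2 * g + 0.5)
  expect_equal(grid_components(coarse, 26), 1)
})

test_that("melt sweeps flag degenerate scales and are deterministic", {
  slab <- make_slab(20, 20, 1)
  melt <- melt_sweep(slab, c(0.5, 1, 2))
  expect_false(any(vapply(melt$realisations, `[[`, TRUE, "degenerate")))
  melt2 <- melt_sweep(slab, c(1, 11), min_voxels = 8)  # 2x2x1 boxes at 11mm
  flags <- vapply(melt2$realisations, `[[`, TRUE, "degenerate")
  expect_true(flags[2])
  pair <- make_sphere_shell(6, 2, 2)
  expect_error(melt_sweep(slab, c(1, 1)), "strictly increasing")
  # jittered grids: identical seed gives bitwise-identical occupancy
  a <- voxelise_ribbon(pair, 0.9, "jitter", seed = 11)
  b <- voxelise_ribbon(pair, 0.9, "jitter", seed = 11)
  expect_identical(a$occupancy, b$occupancy)
  expect_error(voxelise_ribbon(pair, 0.9, "jitter"), "seed")
})

test_that("default scale grid is log-spaced within sane bounds", {
  pair <- make_sphere_shell(10, 2, 3)
  sc <- default_scales(pair, n = 20)
  expect_length(sc, 20)
  expect_true(all(diff(sc) > 0))
  expect_equal(max(sc), 20 / 4 * 2 / 2, tolerance = 1e-9) # quarter of 20mm bbox
  expect_equal(diff(range(diff(log10(sc)))), 0, tolerance = 1e-12)
})
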