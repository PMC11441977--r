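test_that("analytic fixtures match closed-form area and volume", {
  cube <- make_cube(3)
  expect_equal(mesh_area(cube), 54)
  expect_equal(mesh_volume(cube), 27)
  slab <- make_slab(20, 20, 1)
  expect_equal(mesh_area(slab), 2 * 400 + 4 * 20)
  expect_equal(mesh_volume(slab), 400)
  sp <- icosphere(4, 10)
  expect_lt(abs(mesh_area(sp) / (4 * pi * 100) - 1), 0.005)
  expect_lt(abs(mesh_volume(sp) / (4 / 3 * pi * 1000) - 1), 0.005)
})

test_that("degenerate faces are dropped with a warning, not an error", {
  cube <- make_cube(1)
  V <- cube$vertices
  F <- rbind(cube$faces, c(1L, 1L, 2L))
  expect_warning(m <- mesh3(V, F), "degenerate")
  expect_equal(nrow(m$faces), 12)
  expect_error(mesh3(V, cbind(1L, 1L, 1L)), "degenerate")
  expect_error(mesh3(V, rbind(c(1L, 2L, 99L))), "out of range")
})

test_that("orientation repair makes winding consistent and outward", {
  cube <- make_cube(2)
  flipped <- cube
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_lt(mesh_volume(flipped), 0)
  fixed <- orient_mesh(flipped, quiet = TRUE)
  expect_equal(mesh_volume(fixed), 8)
  # scramble individual faces
  scr <- cube
  odd <- seq(1, 12, 2)
  scr$faces[odd, ] <- scr$faces[odd, c(1, 3, 2)]
  fixed2 <- suppressMessages(orient_mesh(scr))
  expect_equal(mesh_volume(fixed2), 8)
  expect_true(mesh_edge_report(fixed2)$watertight)
})

test_that("watertightness report detects open and closed meshes", {
  cube <- make_cube(1)
  expect_true(mesh_edge_report(cube)$watertight)
  open <- cube
  open$faces <- open$faces[-1, ]
  rep <- mesh_edge_report(open)
  expect_false(rep$watertight)
  expect_equal(rep$n_boundary_edges, 3)
})

test_that("convex hull area and volume are exact for boxes and tight for spheres", {
  cube <- make_cube(4)
  expect_equal(convex_hull_area(cube), 96, tolerance = 1e-12)
  expect_equal(convex_hull_volume(cube), 64, tolerance = 1e-12)
  # interior points must not change the hull
  pts <- rbind(cube$vertices, matrix(runif(300, -1.9, 1.9), ncol = 3))
  expect_equal(cortexscale:::cs_hull(pts)$area, 96, tolerance = 1e-9)
  sp <- icosphere(4, 7)
  expect_equal(convex_hull_area(sp), mesh_area(sp), tolerance = 1e-9)
})

test_that("point-in-mesh parity test is exact for analytic shapes", {
  cube <- make_cube(2) # [-1, 1]^3
  pts <- rbind(c(0, 0, 0), c(0.9, 0.9, 0.9), c(1.5, 0, 0), c(-2, -2, -2),
               c(0, 0, 0.999))
  expect_equal(points_in_mesh(pts, cube), c(TRUE, TRUE, FALSE, FALSE, TRUE))
  sp <- icosphere(3, 5)
  set.seed(1)
  q <- matrix(rnorm(300), ncol = 3)
  r <- sqrt(rowSums(q^2))
  # stay away from the triangulated boundary (inscribed polyhedron)
  inside <- r < 4.5
  q[!inside, ] <- q[!inside, ] / r[!inside] * 5.5
  expect_equal(points_in_mesh(q, sp), inside)
})

test_that("taubin smoothing approximately preserves enclosed volume", {
  g <- voxelise_ribbon(icosphere(3, 8), 0.8)
  s <- extract_surfaces(g, "marching")
  v0 <- mesh_volume(s$outer)
  sm <- taubin_smooth(s$outer, 10)
  expect_lt(abs(mesh_volume(sm) / v0 - 1), 0.01)
})

test_that("symmetric surface distance is exact for concentric tessellations", {
  pair <- make_sphere_shell(10, 2, 3)
  d <- symmetric_surface_distance(pair$pial, pair$white)
  expect_lt(abs(d - 2), 0.01)
  # pial -> white direction alone is exactly the shell thickness
  d_pw <- cortexscale:::cs_point_mesh_distance(pair$pial$vertices, pair$white$vertices,
                                 pair$white$faces - 1L)
  expect_equal(max(abs(d_pw - 2)), 0, tolerance = 1e-9)
})
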