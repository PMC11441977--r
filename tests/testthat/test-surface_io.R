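test_that("OFF reading: unit cube, inverted cube, open cube", {
  f <- withr::local_tempfile(fileext = ".off")
  fixture_unit_cube_off(f)
  m <- read_surface(f, quiet = TRUE)
  expect_s3_class(m, "cs_mesh")
  expect_equal(mesh_volume(m), 1.0, tolerance = 1e-12)
  expect_equal(mesh_area(m), 6.0, tolerance = 1e-12)

  # invert every face: orientation must be repaired to outward on load
  txt <- readLines(f)
  faces <- txt[grepl("^3 ", txt)]
  inv <- vapply(strsplit(faces, " "), function(w)
    paste(w[c(1, 2, 4, 3)], collapse = " "), "")
  writeLines(c(txt[!grepl("^3 ", txt)], inv), f)
  m2 <- suppressMessages(read_surface(f))
  expect_equal(mesh_volume(m2), 1.0, tolerance = 1e-12)

  # delete one face: watertightness validation error naming the defect
  writeLines(c("OFF", "8 11 0", txt[3:10], faces[-1]), f)
  expect_error(read_surface(f, quiet = TRUE), "not watertight")
})

test_that("OFF and PLY writers round-trip within float precision", {
  m <- icosphere(2, 3.7)
  for (ext in c(".off", ".ply")) {
    f <- withr::local_tempfile(fileext = ext)
    write_surface(m, f)
    m2 <- read_surface(f, quiet = TRUE)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(mesh_volume(m2), mesh_volume(m), tolerance = 1e-12)
  }
})

test_that("binary little-endian PLY is read correctly", {
  m <- make_cube(2)
  f <- withr::local_tempfile(fileext = ".ply")
  con <- file(f, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               sprintf("element vertex %d", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(m$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeBin(as.numeric(t(m$vertices)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(m$faces))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4L, endian = "little")
  }
  close(con)
  m2 <- read_surface(f, quiet = TRUE)
  expect_equal(mesh_volume(m2), 8, tolerance = 1e-6)
  expect_equal(nrow(m2$faces), 12)
})

test_that("ascii and binary STL are read with vertex merging", {
  m <- make_cube(1.5)
  # ascii
  fa <- withr::local_tempfile(fileext = ".stl")
  lines <- c("solid cube")
  for (i in seq_len(nrow(m$faces))) {
    tri <- m$vertices[m$faces[i, ], , drop = FALSE]
    lines <- c(lines, "facet normal 0 0 0", "outer loop",
               apply(tri, 1, function(r) paste("vertex", paste(r, collapse = " "))),
               "endloop", "endfacet")
  }
  writeLines(c(lines, "endsolid cube"), fa)
  ma <- read_surface(fa, quiet = TRUE)
  expect_equal(nrow(ma$vertices), 8)
  expect_equal(mesh_volume(ma), 1.5^3, tolerance = 1e-9)
  # binary
  fb <- withr::local_tempfile(fileext = ".stl")
  con <- file(fb, "wb")
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(m$faces)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(m$faces))) {
    tri <- m$vertices[m$faces[i, ], , drop = FALSE]
    writeBin(as.numeric(c(0, 0, 0, t(tri))), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
  close(con)
  mb <- read_surface(fb, quiet = TRUE)
  expect_equal(mesh_volume(mb), 1.5^3, tolerance = 1e-6)
})

test_that("FreeSurfer binary surfaces round-trip and parse a hand-built file", {
  m <- icosphere(2, 9)
  f <- withr::local_tempfile()
  write_fs_surface(m, f)
  m2 <- read_surface(f, format = "freesurfer", quiet = TRUE)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(m2$faces, m$faces, ignore_attr = TRUE)

  # independently constructed byte stream (tetrahedron), big-endian layout
  f2 <- withr::local_tempfile()
  con <- file(f2, "wb")
  writeBin(as.raw(c(0xff, 0xff, 0xfe)), con)
  writeBin(charToRaw("made by hand\n\n"), con)
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  F <- rbind(c(0, 2, 1), c(0, 1, 3), c(1, 2, 3), c(0, 3, 2))
  writeBin(4L, con, size = 4, endian = "big")
  writeBin(4L, con, size = 4, endian = "big")
  writeBin(as.numeric(t(V)), con, size = 4, endian = "big")
  writeBin(as.integer(t(F)), con, size = 4, endian = "big")
  close(con)
  tet <- read_surface(f2, quiet = TRUE)   # auto-detected via magic
  expect_equal(nrow(tet$vertices), 4)
  expect_equal(mesh_volume(tet), 1 / 6, tolerance = 1e-7)
})

test_that("validate_pair reports containment and orientation", {
  pair <- make_sphere_shell(10, 2, 2)
  rep <- validate_pair(pair)
  expect_true(rep$ok)
  expect_true(rep$containment)
  # white surface translated outside the pial: flagged, not an error
  bad <- pair
  bad$white <- translate_mesh(bad$white, c(15, 0, 0))
  rep2 <- validate_pair(bad)
  expect_false(rep2$ok)
  expect_false(rep2$containment)
  # empty mesh is a hard error
  broken <- pair
  broken$white$faces <- broken$white$faces[0, , drop = FALSE]
  expect_error(validate_pair(broken), "empty")
})

test_that("occupancy grids round-trip through JSON and NIfTI", {
  occ <- array(FALSE, c(4, 4, 4))
  occ[2, 3, 2] <- TRUE
  g <- cortexscale:::new_grid(origin = c(-1.5, 0.25, 2), spacing = 2.5,
                              occupancy = occ)
  fj <- withr::local_tempfile(fileext = ".json")
  write_grid(g, fj)
  gj <- read_grid(fj)
  expect_identical(gj$occupancy, g$occupancy)
  expect_identical(gj$origin, g$origin)
  expect_identical(gj$spacing, g$spacing)

  fn <- withr::local_tempfile(fileext = ".nii")
  write_grid(g, fn)
  gn <- read_grid(fn)
  expect_identical(gn$occupancy, g$occupancy)
  expect_equal(gn$spacing, 2.5)          # exact in float32
  expect_equal(gn$origin, g$origin, tolerance = 1e-6)

  # all-empty grid writes and reads back with N = 0
  g0 <- cortexscale:::new_grid(c(0, 0, 0), 1, array(FALSE, c(3, 3, 3)))
  f0 <- withr::local_tempfile(fileext = ".json")
  write_grid(g0, f0)
  expect_equal(read_grid(f0)$n_occupied, 0)
})
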