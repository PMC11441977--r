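# shared small fixtures, built in code

fixture_unit_cube_off <- function(path) {
  writeLines(c(
    "OFF",
    "8 12 0",
    "0 0 0", "1 0 0", "0 1 0", "1 1 0",
    "0 0 1", "1 0 1", "0 1 1", "1 1 1",
    # outward-wound faces of the unit cube
    "3 0 2 6", "3 0 6 4",
    "3 1 5 7", "3 1 7 3",
    "3 0 4 5", "3 0 5 1",
    "3 2 3 7", "3 2 7 6",
    "3 0 1 3", "3 0 3 2",
    "3 4 6 7", "3 4 7 5"), path)
  path
}

# two parallel boxes separated by a gap g along x (single watertight mesh
# with two components): the ridge-pair fixture for erasure tests
fixture_two_ridges <- function(g = 2, side = 8, thick = 1) {
  a <- make_slab(thick, side, side, centre = c(-(g + thick) / 2, 0, 0))
  b <- make_slab(thick, side, side, centre = c((g + thick) / 2, 0, 0))
  merge_meshes(a, b, name = sprintf("two ridges gap=%g", g))
}

# a synthetic trajectory data frame with given K/S columns
fixture_traj <- function(K, S, lambda = seq_along(K)) {
  d <- data.frame(lambda = lambda, K = K, S = S, native = FALSE)
  class(d) <- c("cs_trajectory", "data.frame")
  d
}
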