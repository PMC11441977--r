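#' Triangulated surface meshes
#'
#' `mesh3()` builds a triangle mesh from a numeric vertex matrix and an
#' integer face matrix. Meshes are the raw geometry handled throughout the
#' package: closed pial/white cortical surfaces, coarse-grained surfaces
#' extracted from occupancy grids, and synthetic fixtures.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param name free-text label carried through outputs.
#' @param validate drop degenerate (zero-area) faces and check index bounds.
#' @return an object of class `cs_mesh` with elements `vertices`, `faces`,
#'   `name`.
#' @export
mesh3 <- function(vertices, faces, name = "mesh", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(vertices) < 3L || nrow(faces) < 1L) stop("empty mesh")
  if (validate) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    a <- face_areas(vertices, faces)
    degen <- a <= .Machine$double.eps * max(a)
    if (any(degen)) {
      warning(sprintf("dropping %d degenerate faces", sum(degen)))
      faces <- faces[!degen, , drop = FALSE]
      if (nrow(faces) == 0L) stop("all faces degenerate")
    }
  }
  structure(list(vertices = vertices, faces = faces, name = name),
            class = "cs_mesh")
}

#' @export
print.cs_mesh <- function(x, ...) {
  cat(sprintf("<cs_mesh '%s': %d vertices, %d faces, area %.4g, volume %.4g>\n",
              x$name, nrow(x$vertices), nrow(x$faces),
              mesh_area(x), mesh_volume(x)))
  invisible(x)
}

face_areas <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Mesh surface area and enclosed volume
#'
#' Area is the sum of triangle areas; volume is the signed divergence-theorem
#' volume (positive for consistently outward-oriented closed meshes).
#'
#' @param mesh a `cs_mesh`.
#' @return scalar, mm^2 / mm^3.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' @rdname mesh_area
#' @param signed return the signed volume (default takes no absolute value so
#'   that inverted meshes are detectable).
#' @export
mesh_volume <- function(mesh, signed = TRUE) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  v <- sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
           a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
           a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  if (signed) v else abs(v)
}

#' Watertightness and manifoldness report
#'
#' A mesh is watertight (closed, 2-manifold) when every undirected edge is
#' shared by exactly two faces.
#'
#' @param mesh a `cs_mesh`.
#' @return list with `watertight`, `n_edges`, `n_boundary_edges`,
#'   `n_nonmanifold_edges`.
#' @export
mesh_edge_report <- function(mesh) {
  st <- cs_edge_stats(nrow(mesh$vertices), mesh$faces - 1L)
  st$watertight <- st$n_boundary_edges == 0L && st$n_nonmanifold_edges == 0L
  st
}

#' Repair face orientation
#'
#' Makes the winding consistent within each connected component (breadth-first
#' propagation over shared edges), then flips the whole mesh if the signed
#' volume is negative so that normals point outward. Inside/outside tests
#' downstream require this.
#'
#' @param mesh a `cs_mesh`.
#' @param quiet suppress the repair message.
#' @return the repaired mesh.
#' @export
orient_mesh <- function(mesh, quiet = FALSE) {
  res <- cs_orient_faces(nrow(mesh$vertices), mesh$faces - 1L)
  mesh$faces <- res$faces + 1L
  nflip <- res$n_flipped
  if (mesh_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
    nflip <- nflip + nrow(mesh$faces)
  }
  if (nflip > 0L && !quiet)
    message(sprintf("orient_mesh: flipped %d faces to outward orientation", nflip))
  mesh
}

#' Scale, translate
#'
#' @param mesh a `cs_mesh`.
#' @param s scalar isometric scale factor.
#' @export
scale_mesh <- function(mesh, s) {
  mesh$vertices <- mesh$vertices * s
  mesh
}

#' @rdname scale_mesh
#' @param v length-3 translation (mm).
#' @export
translate_mesh <- function(mesh, v) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(v), "+")
  mesh
}

#' Merge meshes into one (disjoint union of components)
#' @param ... `cs_mesh` objects.
#' @param name label of the result.
#' @export
merge_meshes <- function(..., name = "merged") {
  ms <- list(...)
  offs <- cumsum(c(0L, vapply(ms, function(m) nrow(m$vertices), 1L)))
  V <- do.call(rbind, lapply(ms, `[[`, "vertices"))
  F <- do.call(rbind, Map(function(m, o) m$faces + o, ms, offs[seq_along(ms)]))
  mesh3(V, F, name = name)
}

#' Convex hull area of a mesh or point cloud
#'
#' Area of the 3D convex hull ("cling-film" wrap); this is the exposed area
#' Ae of a cortical surface.
#'
#' @param x a `cs_mesh` or a numeric n x 3 matrix of points.
#' @return hull surface area (mm^2).
#' @export
convex_hull_area <- function(x) {
  P <- if (inherits(x, "cs_mesh")) x$vertices else as.matrix(x)
  cs_hull(P)$area
}

#' @rdname convex_hull_area
#' @export
convex_hull_volume <- function(x) {
  P <- if (inherits(x, "cs_mesh")) x$vertices else as.matrix(x)
  cs_hull(P)$volume
}

#' Taubin lambda/mu smoothing
#'
#' Two-step low-pass mesh smoothing that, unlike plain Laplacian smoothing,
#' approximately preserves enclosed volume (shrink step followed by an
#' inflate step). Used to remove voxelisation staircase artefacts from
#' extracted iso-surfaces.
#'
#' @param mesh a `cs_mesh`.
#' @param iterations number of lambda+mu passes.
#' @param lambda shrink factor (0 < lambda < 1).
#' @param mu inflate factor (mu < -lambda for the Taubin band-pass condition).
#' @return smoothed mesh.
#' @export
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.33, mu = -0.34) {
  if (iterations <= 0L) return(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  n <- nrow(V)
  ij <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  ij <- rbind(ij, ij[, c(2, 1)])
  A <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1, dims = c(n, n))
  A@x[] <- 1  # collapse duplicate edge entries to simple adjacency
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  W <- Matrix::Diagonal(x = 1 / deg) %*% A
  for (it in seq_len(iterations)) {
    V <- V + lambda * (as.matrix(W %*% V) - V)
    V <- V + mu * (as.matrix(W %*% V) - V)
  }
  mesh$vertices <- V
  mesh
}

#' Mean symmetric surface-to-surface distance
#'
#' Mean over the vertices of `a` of the exact distance to the closest point on
#' any triangle of `b`, averaged with the reverse direction. This is the
#' native-scale cortical thickness estimator for a pial/white pair.
#'
#' @param a,b `cs_mesh` objects.
#' @return scalar distance (mm).
#' @export
symmetric_surface_distance <- function(a, b) {
  d_ab <- cs_point_mesh_distance(a$vertices, b$vertices, b$faces - 1L)
  d_ba <- cs_point_mesh_distance(b$vertices, a$vertices, a$faces - 1L)
  (mean(d_ab) + mean(d_ba)) / 2
}

#' Are points inside a closed mesh?
#'
#' Ray-parity (even-odd crossing) test with deterministic retry directions for
#' degenerate hits.
#'
#' @param points n x 3 matrix.
#' @param mesh closed `cs_mesh`.
#' @return logical vector.
#' @export
points_in_mesh <- function(points, mesh) {
  cs_points_in_mesh(as.matrix(points), mesh$vertices, mesh$faces - 1L)
}

mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

mean_edge_length <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  d <- V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}
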