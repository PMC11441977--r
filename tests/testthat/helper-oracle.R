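# Brute-force voxelisation oracle, independent of the package's C++ path:
# every voxel is classified directly (no flood fill, no component reuse) as
#   occupied(mesh)  <=> strict triangle-box overlap  OR  centre inside mesh
# with the centre parity computed by vectorised ray casting in R.

oracle_tri_box_strict <- function(ctr, h, t0, t1, t2) {
  t0 <- t0 - ctr; t1 <- t1 - ctr; t2 <- t2 - ctr
  mn <- pmin(t0, t1, t2); mx <- pmax(t0, t1, t2)
  if (any(mn > h) || any(mx < -h)) return(FALSE)
  e0 <- t1 - t0; e1 <- t2 - t1; e2 <- t0 - t2
  n <- c(e0[2] * e1[3] - e0[3] * e1[2],
         e0[3] * e1[1] - e0[1] * e1[3],
         e0[1] * e1[2] - e0[2] * e1[1])
  if (abs(sum(n * t0)) > sum(h * abs(n))) return(FALSE)
  verts <- rbind(t0, t1, t2)
  for (e in list(e0, e1, e2)) {
    # axis cross(x, e)
    p <- -e[3] * verts[, 2] + e[2] * verts[, 3]
    r <- h[2] * abs(e[3]) + h[3] * abs(e[2])
    if (min(p) > r || max(p) < -r) return(FALSE)
    p <- e[3] * verts[, 1] - e[1] * verts[, 3]
    r <- h[1] * abs(e[3]) + h[3] * abs(e[1])
    if (min(p) > r || max(p) < -r) return(FALSE)
    p <- -e[2] * verts[, 1] + e[1] * verts[, 2]
    r <- h[1] * abs(e[2]) + h[2] * abs(e[1])
    if (min(p) > r || max(p) < -r) return(FALSE)
  }
  TRUE
}

# strict-overlap mask over the grid for one mesh
oracle_strict_mask <- function(mesh, origin, spacing, dims) {
  V <- mesh$vertices; F <- mesh$faces
  out <- array(FALSE, dims)
  h <- rep(spacing / 2 - 1e-9 * spacing, 3)
  for (f in seq_len(nrow(F))) {
    tri <- V[F[f, ], , drop = FALSE]
    lo <- pmax(1, floor((apply(tri, 2, min) - origin) / spacing - 1e-9) + 1)
    hi <- pmin(dims, floor((apply(tri, 2, max) - origin) / spacing + 1e-9) + 1)
    if (any(lo > hi)) next
    for (k in lo[3]:hi[3]) for (j in lo[2]:hi[2]) for (i in lo[1]:hi[1]) {
      if (out[i, j, k]) next
      ctr <- origin + (c(i, j, k) - 0.5) * spacing
      if (oracle_tri_box_strict(ctr, h, tri[1, ], tri[2, ], tri[3, ]))
        out[i, j, k] <- TRUE
    }
  }
  out
}

# parity of ray crossings for a matrix of points, vectorised per triangle
oracle_points_inside <- function(P, mesh,
                                 dirs = list(c(0.2873479, 0.4417231, 0.8499095),
                                             c(0.7071068, 0.4082483, 0.5773503),
                                             c(0.1690309, 0.8451543, 0.5070926))) {
  V <- mesh$vertices; F <- mesh$faces
  n <- nrow(P)
  res <- rep(NA, n)
  todo <- rep(TRUE, n)
  for (d in dirs) {
    if (!any(todo)) break
    pts <- P[todo, , drop = FALSE]
    cnt <- rep(0L, nrow(pts))
    bad <- rep(FALSE, nrow(pts))
    for (f in seq_len(nrow(F))) {
      a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; cc <- V[F[f, 3], ]
      e1 <- b - a; e2 <- cc - a
      pv <- c(d[2] * e2[3] - d[3] * e2[2],
              d[3] * e2[1] - d[1] * e2[3],
              d[1] * e2[2] - d[2] * e2[1])
      det <- sum(e1 * pv)
      if (abs(det) < 1e-14) next
      tv <- sweep(pts, 2, a)
      u <- (tv %*% pv) / det
      qv <- cbind(tv[, 2] * e1[3] - tv[, 3] * e1[2],
                  tv[, 3] * e1[1] - tv[, 1] * e1[3],
                  tv[, 1] * e1[2] - tv[, 2] * e1[1])
      v <- (qv %*% d) / det
      tt <- (qv %*% e2) / det
      hit <- u > 1e-9 & v > 1e-9 & (u + v) < 1 - 1e-9 & tt > 1e-9
      graze <- tt > 1e-9 &
        u > -1e-7 & v > -1e-7 & (u + v) < 1 + 1e-7 & !hit
      near0 <- abs(tt) <= 1e-9 & u > -1e-7 & v > -1e-7 & (u + v) < 1 + 1e-7
      bad <- bad | graze | near0
      cnt <- cnt + as.integer(hit)
    }
    idx <- which(todo)
    ok <- !bad
    res[idx[ok]] <- (cnt[ok] %% 2L) == 1L
    todo[idx[ok]] <- FALSE
  }
  if (any(todo)) stop("oracle ray casting failed to resolve some points")
  res
}

# full occupancy oracle for a pair (or single mesh) on a given grid geometry.
# Ray classification is only needed (and only well-posed) for voxels without
# strict surface overlap: their centres cannot lie on the surface.
oracle_occupancy <- function(pair, origin, spacing, dims) {
  pair <- cortexscale:::as_pair(pair)
  idx <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                     k = seq_len(dims[3]))
  centres <- sweep(sweep(as.matrix(idx) - 0.5, 2, c(spacing, spacing, spacing), "*"),
                   2, origin, "+")
  classify <- function(mesh) {
    strict <- oracle_strict_mask(mesh, origin, spacing, dims)
    inside <- array(FALSE, dims)
    need <- !as.vector(strict)
    inside[need] <- oracle_points_inside(centres[need, , drop = FALSE], mesh)
    list(strict = strict, inside = inside)
  }
  P <- classify(pair$pial)
  occ <- P$strict | P$inside
  if (!is.null(pair$white)) {
    W <- classify(pair$white)
    occ <- occ & !(!W$strict & W$inside)
  }
  occ
}
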