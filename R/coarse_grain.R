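#' Coarse-graining ("melting") of the cortical ribbon
#'
#' The core operation: segment the space between the pial and white matter
#' surfaces into a 3D grid of cubic boxes of side `lambda`. A box is occupied
#' iff it intersects the ribbon, i.e. iff it intersects the pial solid and is
#' not strictly inside the white solid. The occupancy is conservative (any
#' partial overlap counts), which is what fuses neighbouring gyri whose
#' separation is below `lambda` and so erases folds smaller than the scale.
#'
#' In single-surface mode (a `cs_mesh`, or a pair without a white surface) a
#' box is occupied iff it intersects the mesh interior or boundary.
#'
#' Inside/outside classification is exact for watertight input: boxes touched
#' by any triangle are found by triangle--box overlap tests (separating axis
#' theorem); the remaining boxes are classified per 6-connected component by a
#' ray-parity test at one representative box centre.
#'
#' @param pair a `cs_pair` or a single closed `cs_mesh`.
#' @param lambda box side (mm), `0 < lambda <` largest bounding-box extent.
#' @param origin_policy `"bbox"` aligns the grid to the padded bounding-box
#'   minimum; `"jitter"` additionally shifts the origin by a uniform draw in
#'   `[0, lambda)^3` (seeded), supporting robustness-over-realisations
#'   experiments.
#' @param seed integer seed, mandatory when `origin_policy = "jitter"`.
#' @param pad number of guaranteed empty boxes on every side (>= 1).
#' @return a `cs_grid`: list with `origin` (mm), `spacing` (= lambda, mm),
#'   `occupancy` (logical 3D array), `n_occupied`, `lambda`, `origin_policy`.
#' @export
voxelise_ribbon <- function(pair, lambda, origin_policy = c("bbox", "jitter"),
                            seed = NULL, pad = 1L) {
  pair <- as_pair(pair)
  origin_policy <- match.arg(origin_policy)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a positive scalar")
  bb <- mesh_bbox(pair$pial)
  ext <- bb[2, ] - bb[1, ]
  if (lambda >= max(ext))
    stop(sprintf(
      "lambda = %g would yield <= 1 box; maximum usable lambda is below %g",
      lambda, max(ext)))
  offset <- c(0, 0, 0)
  if (origin_policy == "jitter") {
    if (is.null(seed)) stop("origin_policy = 'jitter' requires a seed")
    offset <- with_seed(as.integer(seed), stats::runif(3)) * lambda
  }
  origin <- bb[1, ] - pad * lambda - offset
  dims <- as.integer(ceiling((bb[2, ] - origin) / lambda) + pad)
  codes_p <- cs_voxelise_codes(pair$pial$vertices, pair$pial$faces - 1L,
                               origin, lambda, dims)
  occ <- codes_p > 0L
  if (!is.null(pair$white)) {
    codes_w <- cs_voxelise_codes(pair$white$vertices, pair$white$faces - 1L,
                                 origin, lambda, dims)
    occ <- occ & codes_w != 2L
  }
  new_grid(origin = as.numeric(origin), spacing = lambda,
           occupancy = array(occ, dim = dims),
           origin_policy = origin_policy, seed = seed)
}

new_grid <- function(origin, spacing, occupancy, origin_policy = "bbox",
                     seed = NULL) {
  structure(list(origin = origin, spacing = spacing, occupancy = occupancy,
                 n_occupied = sum(occupancy), lambda = spacing,
                 origin_policy = origin_policy, seed = seed),
            class = "cs_grid")
}

#' @export
print.cs_grid <- function(x, ...) {
  cat(sprintf("<cs_grid: %s boxes at lambda = %g mm, N = %d occupied>\n",
              paste(dim(x$occupancy), collapse = "x"), x$spacing, x$n_occupied))
  invisible(x)
}

#' Extract coarse-grained surfaces from an occupancy grid
#'
#' Background boxes are partitioned by 6-connected flood fill from the grid
#' border into exterior and interior cavities. The outer (pial-equivalent)
#' surface is the interface between the solid (occupied set plus cavities) and
#' the exterior; the inner (white-equivalent) surface bounds the cavities and
#' is absent once the interior has melted shut.
#'
#' `mode = "faces"` returns exact unions of box faces (areas are integer
#' multiples of lambda^2; the oracle-friendly estimator). `mode = "marching"`
#' returns the iso-surface of the binary occupancy at level 0.5, extracted by
#' marching tetrahedra over the box-centre lattice, optionally Taubin-smoothed.
#'
#' @param grid a `cs_grid` with at least one occupied box.
#' @param mode `"marching"` or `"faces"`.
#' @param smooth_iters Taubin smoothing iterations applied to marching-mode
#'   surfaces (enclosed volume changes by well under 1\% per 10 iterations).
#' @return a `cs_surfaces`: list with `outer` (`cs_mesh`), `inner` (`cs_mesh`
#'   or `NULL`), `lambda`, `mode`, `smooth_iters`.
#' @export
extract_surfaces <- function(grid, mode = c("marching", "faces"),
                             smooth_iters = 0L) {
  mode <- match.arg(mode)
  occ <- grid$occupancy
  if (sum(occ) < 1L) stop("empty grid")
  dims <- dim(occ)
  lab <- cs_label_empty(as.logical(occ), dims)
  cav <- array(lab >= 2L, dim = dims)
  solid <- occ | cav
  extract1 <- function(s) {
    res <- if (mode == "faces")
      cs_faces_mesh(as.logical(s), dims, grid$origin, grid$spacing)
    else
      cs_marching_tets(as.logical(s), dims, grid$origin, grid$spacing)
    if (nrow(res$faces) == 0L) return(NULL)
    m <- mesh3(res$vertices, res$faces + 1L, name = "coarse", validate = FALSE)
    if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
    if (mode == "marching" && smooth_iters > 0L)
      m <- taubin_smooth(m, smooth_iters)
    m
  }
  outer <- extract1(solid)
  inner <- if (any(cav)) extract1(cav) else NULL
  structure(list(outer = outer, inner = inner, lambda = grid$spacing,
                 mode = mode, smooth_iters = smooth_iters),
            class = "cs_surfaces")
}

#' @export
print.cs_surfaces <- function(x, ...) {
  cat(sprintf("<cs_surfaces at lambda = %g (%s mode): outer %d faces%s>\n",
              x$lambda, x$mode, nrow(x$outer$faces),
              if (is.null(x$inner)) ", no inner cavity"
              else sprintf(", inner %d faces", nrow(x$inner$faces))))
  invisible(x)
}

#' Default scale grid
#'
#' 20 values log10-spaced between `lambda_min` (the mean input mesh edge
#' length, floored at 0.25 mm) and `lambda_max` (a quarter of the largest
#' bounding-box extent).
#'
#' @param pair a `cs_pair` or `cs_mesh`.
#' @param n number of scales.
#' @param lambda_min,lambda_max optional overrides (mm).
#' @return numeric vector of scales, strictly increasing.
#' @export
default_scales <- function(pair, n = 20L, lambda_min = NULL, lambda_max = NULL) {
  pair <- as_pair(pair)
  if (is.null(lambda_min))
    lambda_min <- max(mean_edge_length(pair$pial), 0.25)
  if (is.null(lambda_max)) {
    bb <- mesh_bbox(pair$pial)
    lambda_max <- max(bb[2, ] - bb[1, ]) / 4
  }
  if (lambda_max <= lambda_min)
    stop("lambda_max must exceed lambda_min for this object")
  10^seq(log10(lambda_min), log10(lambda_max), length.out = n)
}

#' Melt sweep: coarse-grain at a sequence of scales
#'
#' Runs [voxelise_ribbon()] and [extract_surfaces()] at each scale. Scales at
#' which the object degenerates (fewer than `min_voxels` occupied boxes) are
#' flagged, not dropped. Deterministic given `origin_policy` and `seed`.
#'
#' @inheritParams voxelise_ribbon
#' @inheritParams extract_surfaces
#' @param scales strictly increasing vector of box sides (mm); `NULL` for
#'   [default_scales()].
#' @param min_voxels degeneracy threshold on the occupied box count.
#' @param keep_grids retain the occupancy grids in the result (memory!).
#' @return a `cs_melt`: list of per-scale realisations, each with `lambda`,
#'   `grid` (if kept), `surfaces`, `N`, `degenerate`.
#' @export
melt_sweep <- function(pair, scales = NULL, origin_policy = c("bbox", "jitter"),
                       seed = NULL, mode = c("marching", "faces"),
                       smooth_iters = 0L, min_voxels = 8L, keep_grids = FALSE) {
  pair <- as_pair(pair)
  origin_policy <- match.arg(origin_policy)
  mode <- match.arg(mode)
  if (is.null(scales)) scales <- default_scales(pair)
  if (any(diff(scales) <= 0)) stop("scales must be strictly increasing")
  out <- lapply(scales, function(lam) {
    grid <- voxelise_ribbon(pair, lam, origin_policy, seed = seed)
    degenerate <- grid$n_occupied < min_voxels
    surfaces <- if (grid$n_occupied >= 1L)
      extract_surfaces(grid, mode, smooth_iters) else NULL
    list(lambda = lam, grid = if (keep_grids) grid else NULL,
         surfaces = surfaces, N = grid$n_occupied,
         V = grid$n_occupied * lam^3, degenerate = degenerate)
  })
  structure(list(realisations = out, scales = scales, mode = mode,
                 smooth_iters = smooth_iters, origin_policy = origin_policy,
                 seed = seed),
            class = "cs_melt")
}

#' @export
print.cs_melt <- function(x, ...) {
  nd <- sum(vapply(x$realisations, `[[`, TRUE, "degenerate"))
  cat(sprintf("<cs_melt: %d scales in [%g, %g] mm (%s mode), %d degenerate>\n",
              length(x$scales), min(x$scales), max(x$scales), x$mode, nd))
  invisible(x)
}

#' Count 26-connected components of the occupied set
#' @param grid a `cs_grid`.
#' @param connectivity 26 (default, the complement of the 6-connected
#'   background) or 6.
#' @export
grid_components <- function(grid, connectivity = 26L) {
  cs_count_components(as.logical(grid$occupancy), dim(grid$occupancy),
                      as.integer(connectivity))
}

# run code with a local, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
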