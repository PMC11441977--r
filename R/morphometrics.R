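#' Measure a coarse-grained realisation
#'
#' Computes, at one coarse-graining scale: total (pial-equivalent) area `At`
#' as the triangle-area sum of the outer surface; exposed area `Ae` as the
#' area of the convex hull of the outer surface vertices; ribbon volume
#' `V = N * lambda^3`; and average thickness `T = 2V / (At + Ai)` where `Ai`
#' is the inner-surface area (0 once the cavity has melted shut). The
#' thickness estimator is exact for slabs and concentric shells and remains
#' well defined after the interior cavity disappears.
#'
#' @param surfaces a `cs_surfaces` from [extract_surfaces()].
#' @param grid the matching `cs_grid` (same scale).
#' @return a one-row data frame (`cs_realisation`): `lambda`, `At`, `Ae`,
#'   `Ai`, `T`, `V`, `N`, `mode`, `rescaled`, `s`, `native`.
#' @export
measure_realisation <- function(surfaces, grid) {
  if (is.null(surfaces$outer)) stop("empty outer surface")
  if (!isTRUE(all.equal(surfaces$lambda, grid$spacing)))
    stop("grid and surfaces are at different scales")
  At <- mesh_area(surfaces$outer)
  Ae <- convex_hull_area(surfaces$outer)
  Ai <- if (is.null(surfaces$inner)) 0 else mesh_area(surfaces$inner)
  N <- grid$n_occupied
  V <- N * grid$spacing^3
  T <- 2 * V / (At + Ai)
  new_realisation(lambda = grid$spacing, At = At, Ae = Ae, Ai = Ai,
                  T = T, V = V, N = N,
                  mode = paste0(surfaces$mode,
                                if (surfaces$smooth_iters > 0)
                                  paste0("+taubin", surfaces$smooth_iters) else ""))
}

new_realisation <- function(lambda, At, Ae, Ai, T, V, N, mode,
                            rescaled = FALSE, s = 1, native = FALSE) {
  stopifnot(At > 0, Ae > 0, T > 0, V > 0)
  df <- data.frame(lambda = lambda, At = At, Ae = Ae, Ai = Ai, T = T, V = V,
                   N = N, mode = mode, rescaled = rescaled, s = s,
                   native = native, stringsAsFactors = FALSE)
  class(df) <- c("cs_realisation", "data.frame")
  df
}

#' Measure a pair at native scale
#'
#' `At` and `Ae` from the pial mesh and its convex hull; `V` as the difference
#' of enclosed volumes; `T` as the mean symmetric nearest-surface distance
#' between the pial and white surfaces. Single-surface mode has no native
#' thickness and raises an error.
#'
#' @param pair a `cs_pair` with both surfaces.
#' @return a one-row `cs_realisation` with `native = TRUE` and `lambda = 0`.
#' @export
measure_native <- function(pair) {
  pair <- as_pair(pair)
  if (is.null(pair$white))
    stop("native thickness requires a white surface (single-surface mode has none)")
  At <- mesh_area(pair$pial)
  Ae <- convex_hull_area(pair$pial)
  V <- mesh_volume(pair$pial, signed = FALSE) -
    mesh_volume(pair$white, signed = FALSE)
  T <- symmetric_surface_distance(pair$pial, pair$white)
  new_realisation(lambda = 0, At = At, Ae = Ae, Ai = mesh_area(pair$white),
                  T = T, V = V, N = NA_integer_, mode = "native",
                  native = TRUE)
}

#' Isometric rescaling of a realisation
#'
#' Fixes the box as the unit of length: with `s = lambda_ref / lambda`, areas
#' scale by `s^2`, thickness by `s`, volume by `s^3`. Shrinking the surface
#' relative to the box is equivalent to growing the box, so after rescaling,
#' realisations at different scales are shape-comparable, and thickness
#' decreases under coarse-graining instead of growing. The shape coordinates
#' K and S are invariant under this operation.
#'
#' @param r a `cs_realisation` (unrescaled).
#' @param lambda_ref reference scale (mm), > 0.
#' @return the rescaled realisation (`rescaled = TRUE`, physical `lambda`
#'   retained, factor stored in `s`).
#' @export
rescale_realisation <- function(r, lambda_ref) {
  if (lambda_ref <= 0) stop("lambda_ref must be positive")
  if (any(r$rescaled)) stop("realisation is already rescaled")
  s <- ifelse(r$native, 1, lambda_ref / r$lambda)
  r$At <- r$At * s^2
  r$Ae <- r$Ae * s^2
  r$Ai <- r$Ai * s^2
  r$T <- r$T * s
  r$V <- r$V * s^3
  r$s <- s
  r$rescaled <- TRUE
  r
}

#' K, I, S shape coordinates
#'
#' Orthogonal linear combinations (log10) of total area, exposed area and
#' squared thickness:
#' \deqn{K = \log At - \frac{5}{4}\log Ae + \frac{1}{4}\log T^2}
#' \deqn{I = \log At + \log Ae + \log T^2}
#' \deqn{S = \frac{3}{2}\log At + \frac{3}{4}\log Ae - \frac{9}{4}\log T^2}
#' K is the direction of the scaling-law offset k, I the isometric size, and
#' S a measure of morphological complexity. K and S are invariant under
#' isometric scaling; I shifts by `6 log10 c` under scaling by `c`. The
#' coefficient vectors over (log At, log Ae, log T^2) are mutually orthogonal.
#'
#' @param At,Ae,T positive numerics (recycled).
#' @param normalised divide each coordinate by the Euclidean norm of its
#'   coefficient vector (`sqrt(42)/4`, `sqrt(3)`, `sqrt(126)/4`), giving the
#'   normalised K x S plane.
#' @return data frame with columns `K`, `I`, `S`, `normalised`.
#' @export
kis_coordinates <- function(At, Ae, T, normalised = FALSE) {
  if (any(At <= 0) || any(Ae <= 0) || any(T <= 0))
    stop("At, Ae and T must be positive")
  lAt <- log10(At); lAe <- log10(Ae); lT2 <- log10(T^2)
  K <- lAt - 5 / 4 * lAe + 1 / 4 * lT2
  I <- lAt + lAe + lT2
  S <- 3 / 2 * lAt + 3 / 4 * lAe - 9 / 4 * lT2
  if (normalised) {
    K <- K / (sqrt(42) / 4)
    I <- I / sqrt(3)
    S <- S / (sqrt(126) / 4)
  }
  data.frame(K = K, I = I, S = S, normalised = normalised)
}

#' @rdname kis_coordinates
#' @param r a `cs_realisation` (any number of rows).
#' @export
compute_kis <- function(r, normalised = FALSE) {
  cbind(r, kis_coordinates(r$At, r$Ae, r$T, normalised = normalised))
}

#' K/I/S coefficient vectors over (log At, log Ae, log T^2)
#' @param normalised unit-norm vectors.
#' @return 3 x 3 matrix with rows K, I, S.
#' @export
kis_basis <- function(normalised = FALSE) {
  B <- rbind(K = c(1, -5 / 4, 1 / 4),
             I = c(1, 1, 1),
             S = c(3 / 2, 3 / 4, -9 / 4))
  colnames(B) <- c("logAt", "logAe", "logT2")
  if (normalised) B / sqrt(rowSums(B^2)) else B
}

#' Measure a full melt sweep into a trajectory
#'
#' Measures every non-degenerate realisation of a melt sweep, applies the
#' isometric rescaling to a common reference scale and attaches the K/I/S
#' coordinates, optionally prepending the native-scale point. This is the
#' ordered path of the object through morphometric space as the scale
#' increases.
#'
#' @param melt a `cs_melt` from [melt_sweep()], or a `cs_pair`/`cs_mesh` (in
#'   which case the sweep is run here with `...` passed to [melt_sweep()]).
#' @param lambda_ref reference scale for rescaling (mm); default the smallest
#'   swept scale.
#' @param native optional `cs_realisation` from [measure_native()], or `TRUE`
#'   to measure it from `pair` when available.
#' @param pair the `cs_pair`, required when `native = TRUE`.
#' @param id object identifier carried into group analyses.
#' @param ... passed to [melt_sweep()] when `melt` is a pair.
#' @return a `cs_trajectory` data frame: one row per scale, ascending lambda,
#'   native row (if any) first, with raw (`*_raw`) and rescaled measures plus
#'   `K`, `I`, `S`.
#' @export
measure_sweep <- function(melt, lambda_ref = NULL, native = FALSE, pair = NULL,
                          id = "object", ...) {
  if (inherits(melt, c("cs_pair", "cs_mesh"))) {
    pair <- if (is.null(pair)) as_pair(melt) else pair
    melt <- melt_sweep(melt, ...)
  }
  stopifnot(inherits(melt, "cs_melt"))
  rows <- list()
  if (isTRUE(native)) {
    if (is.null(pair)) stop("native = TRUE requires `pair`")
    rows <- list(measure_native(pair))
  } else if (inherits(native, "cs_realisation")) rows <- list(native)
  for (re in melt$realisations) {
    if (re$degenerate || is.null(re$surfaces)) next
    grid <- re$grid
    if (is.null(grid)) {
      # grids were not kept: reconstruct the measured quantities directly
      r <- local({
        At <- mesh_area(re$surfaces$outer)
        Ae <- convex_hull_area(re$surfaces$outer)
        Ai <- if (is.null(re$surfaces$inner)) 0 else mesh_area(re$surfaces$inner)
        V <- re$V
        new_realisation(lambda = re$lambda, At = At, Ae = Ae, Ai = Ai,
                        T = 2 * V / (At + Ai), V = V, N = re$N,
                        mode = paste0(melt$mode,
                                      if (melt$smooth_iters > 0)
                                        paste0("+taubin", melt$smooth_iters) else ""))
      })
    } else r <- measure_realisation(re$surfaces, grid)
    rows <- c(rows, list(r))
  }
  if (length(rows) == 0L) stop("no non-degenerate realisations to measure")
  raw <- do.call(rbind, rows)
  if (is.null(lambda_ref)) {
    lam <- raw$lambda[!raw$native]
    lambda_ref <- if (length(lam)) min(lam) else 1
  }
  resc <- rescale_realisation(raw, lambda_ref)
  out <- resc
  for (col in c("At", "Ae", "Ai", "T", "V")) out[[paste0(col, "_raw")]] <- raw[[col]]
  out <- compute_kis(out)
  out$lambda_ref <- lambda_ref
  out$id <- id
  out <- out[order(!out$native, out$lambda), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cs_trajectory", "data.frame")
  out
}
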