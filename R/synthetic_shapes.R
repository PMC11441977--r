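#' Axis-aligned box mesh
#'
#' Closed, outward-oriented box (12 triangles), the convex reference object:
#' a slab of finite thickness has `Ae = At` at every coarse-graining scale and
#' therefore lies on the `K = -S/9` line.
#'
#' @param lx,ly,lz side lengths (mm).
#' @param centre length-3 centre (mm).
#' @return a `cs_mesh`.
#' @export
make_slab <- function(lx = 20, ly = 20, lz = 1, centre = c(0, 0, 0)) {
  if (any(c(lx, ly, lz) <= 0)) stop("box dimensions must be positive")
  h <- c(lx, ly, lz) / 2
  v <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  V <- sweep(v * rep(h, each = 8), 2, centre, "+")
  # faces of the unit cube on expand.grid ordering (1-based), outward winding
  F <- rbind(
    c(1, 3, 7), c(1, 7, 5),   # -x
    c(2, 6, 8), c(2, 8, 4),   # +x
    c(1, 5, 6), c(1, 6, 2),   # -y
    c(3, 4, 8), c(3, 8, 7),   # +y
    c(1, 2, 4), c(1, 4, 3),   # -z
    c(5, 7, 8), c(5, 8, 6)    # +z
  )
  orient_mesh(mesh3(V, F, name = sprintf("slab %gx%gx%g", lx, ly, lz)),
              quiet = TRUE)
}

#' @rdname make_slab
#' @param a cube side (mm).
#' @export
make_cube <- function(a = 10, centre = c(0, 0, 0)) {
  m <- make_slab(a, a, a, centre)
  m$name <- sprintf("cube %g", a)
  m
}

#' Icosphere
#'
#' Subdivided icosahedron projected onto the sphere; the standard high-quality
#' sphere triangulation (20 * 4^subdiv faces).
#'
#' @param subdiv subdivision level (>= 0).
#' @param r radius (mm).
#' @param centre length-3 centre.
#' @return a `cs_mesh`.
#' @export
icosphere <- function(subdiv = 4L, r = 1, centre = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(1 + phi^2)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    nv <- nrow(V)
    e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- (e[, 1] - 1) * nv + e[, 2]
    ukey <- unique(key)
    mid_idx <- nv + match(key, ukey)
    ue <- e[!duplicated(key), , drop = FALSE]
    mids <- (V[ue[, 1], , drop = FALSE] + V[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    V <- rbind(V, mids)
    nf <- nrow(F)
    m12 <- mid_idx[seq_len(nf)]
    m23 <- mid_idx[nf + seq_len(nf)]
    m31 <- mid_idx[2 * nf + seq_len(nf)]
    F <- rbind(cbind(F[, 1], m12, m31),
               cbind(F[, 2], m23, m12),
               cbind(F[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  V <- sweep(V * r, 2, centre, "+")
  orient_mesh(mesh3(V, F, name = sprintf("icosphere r=%g s=%d", r, subdiv)),
              quiet = TRUE)
}

#' Concentric sphere shell
#'
#' Pial sphere of radius `r` and white sphere of radius `r-t`, same
#' tessellation: a lissencephalic reference with closed-form areas and exact
#' native thickness `t`.
#'
#' @param r outer (pial) radius (mm).
#' @param t shell thickness (mm), `0 < t < r`.
#' @param subdiv icosphere subdivision level.
#' @return a `cs_pair`.
#' @export
make_sphere_shell <- function(r = 10, t = 2, subdiv = 4L) {
  if (t <= 0 || t >= r) stop("need 0 < t < r")
  surface_pair(icosphere(subdiv, r), icosphere(subdiv, r - t),
               hemisphere = "synthetic")
}

# sum of randomly oriented spherical plane waves at one angular frequency;
# unit rms, deterministic given the RNG state
band_field <- function(u, f, waves = 6L) {
  J <- waves
  dirs <- matrix(stats::rnorm(3 * J), J, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  phases <- stats::runif(J, 0, 2 * pi)
  z <- u %*% t(dirs) * f
  vals <- sweep(z, 2, phases, "+")
  rowSums(sqrt(2 / J) * cos(vals))
}

#' Folded spherical shell with a controlled fold spectrum
#'
#' The pial surface is a sphere of radius `R` radially displaced by a
#' superposition of spherical sinusoids: for each spectrum row (angular
#' frequency `f`, amplitude `a`), a sum of randomly oriented plane waves
#' `cos(f * w_j . u + phi_j)` with unit rms is scaled to rms amplitude `a`.
#' The fold wavelength of a band is approximately `2 pi R / f`: this is the
#' controllable feature size erased when the coarse-graining scale exceeds
#' it. The white surface is the same radial graph offset inward by `t`
#' (`r_white = r_pial - t`), which for star-shaped shells cannot
#' self-intersect and keeps the shell thickness uniform along the radius.
#'
#' @param R base sphere radius (mm).
#' @param folds data frame with columns `frequency` (angular) and `amplitude`
#'   (rms radial displacement, mm); empty/NULL recovers the plain shell.
#' @param t shell thickness (mm).
#' @param subdiv icosphere subdivision level (mesh edge must resolve the
#'   smallest fold wavelength).
#' @param seed integer seed for wave directions and phases (mandatory when
#'   folds are present).
#' @param waves number of plane waves per band.
#' @return a `cs_pair` with attribute `"spec"` recording the generator inputs.
#' @export
make_sinusoid_shell <- function(R = 10, folds = NULL, t = 1, subdiv = 4L,
                                seed = NULL, waves = 6L) {
  if (t <= 0 || t >= R) stop("need 0 < t < R")
  base <- icosphere(subdiv, 1)
  u <- base$vertices
  d <- rep(0, nrow(u))
  if (!is.null(folds) && nrow(folds) > 0) {
    if (is.null(seed)) stop("folded shells require a seed")
    if (any(folds$amplitude < 0)) stop("amplitudes must be >= 0")
    d <- with_seed(as.integer(seed), {
      acc <- rep(0, nrow(u))
      for (i in seq_len(nrow(folds)))
        acc <- acc + folds$amplitude[i] * band_field(u, folds$frequency[i], waves)
      acc
    })
    if (max(abs(d)) >= R / 2)
      stop(sprintf(
        "maximum radial displacement %.3g exceeds R/2 = %.3g; reduce amplitudes",
        max(abs(d)), R / 2))
  }
  r_pial <- R + d
  r_white <- r_pial - t
  if (any(r_white <= 0)) stop("white surface radius would be non-positive")
  pial <- base; pial$vertices <- u * r_pial; pial$name <- "sinusoid pial"
  white <- base; white$vertices <- u * r_white; white$name <- "sinusoid white"
  p <- surface_pair(pial, white, hemisphere = "synthetic")
  attr(p, "spec") <- list(kind = "sinusoid_shell", R = R, folds = folds, t = t,
                          subdiv = subdiv, seed = seed, waves = waves)
  p
}

#' Fractal shell with prescribed Hurst exponent
#'
#' The radial displacement field is synthesised spectrally as a sum of
#' log-spaced frequency octaves with per-octave rms proportional to
#' `wavelength^H` (power spectral density proportional to
#' `frequency^(-2(H+1))`), i.e. a fractional-Brownian-motion-like surface
#' whose graph has fractal dimension `3 - H` over the resolved band.
#' `H = 0.5` gives the cortical value `df = 2.5`. Synthesis is restricted to
#' wavelengths between `band[1]` and `band[2]` (defaults: 4 x mesh edge
#' length and `R/2`); the fractal dimension is only meaningful over this
#' band. Deterministic given the seed.
#'
#' @param R base radius (mm).
#' @param H Hurst exponent in (0, 1).
#' @param amplitude total rms radial displacement (mm).
#' @param t shell thickness (mm).
#' @param subdiv icosphere subdivision level.
#' @param seed mandatory integer seed.
#' @param band `c(min, max)` wavelength band (mm).
#' @param waves plane waves per octave.
#' @param octaves_per_doubling frequency resolution of the synthesis.
#' @return a `cs_pair` with attribute `"spec"`.
#' @export
make_fbm_shell <- function(R = 20, H = 0.5, amplitude = R / 2.5, t = 0.5,
                           subdiv = 6L, seed, band = NULL, waves = 12L,
                           octaves_per_doubling = 2L) {
  if (missing(seed) || is.null(seed)) stop("make_fbm_shell requires a seed")
  if (H <= 0 || H >= 1) stop("H must be in (0, 1)")
  if (t <= 0 || t >= R) stop("need 0 < t < R")
  base <- icosphere(subdiv, 1)
  u <- base$vertices
  if (is.null(band)) band <- c(4 * mean_edge_length(base) * R, R / 2)
  if (band[1] >= band[2]) stop("empty wavelength band; increase subdiv or R")
  step <- 2^(1 / octaves_per_doubling)
  wl <- band[2] / step^(0:floor(log(band[2] / band[1], step)))
  sig <- wl^H
  sig <- sig / sqrt(sum(sig^2)) * amplitude
  d <- with_seed(as.integer(seed), {
    acc <- rep(0, nrow(u))
    for (i in seq_along(wl)) {
      f <- 2 * pi * R / wl[i] # angular frequency on the unit sphere
      acc <- acc + sig[i] * band_field(u, f, waves)
    }
    acc
  })
  # a radial graph r(u) > 0 is star-shaped for any positive radius, so only
  # the negative Gaussian tail needs clamping (keep the white surface off the
  # origin)
  lim <- -(R - t) * 0.85
  if (any(d < lim)) {
    warning("clamping extreme inward displacements to keep radii positive")
    d <- pmax(d, lim)
  }
  r_pial <- R + d
  pial <- base; pial$vertices <- u * r_pial; pial$name <- "fbm pial"
  white <- base; white$vertices <- u * (r_pial - t); white$name <- "fbm white"
  p <- surface_pair(pial, white, hemisphere = "synthetic")
  attr(p, "spec") <- list(kind = "fbm_shell", R = R, H = H,
                          amplitude = amplitude, t = t, subdiv = subdiv,
                          seed = seed, band = band, waves = waves)
  p
}

#' Two-group synthetic cohort
#'
#' Generates `n_per_group` folded shells per group from a base sinusoid-shell
#' specification. Each subject gets independent (seeded) wave directions and
#' phases plus log-normal amplitude jitter; group B differs from group A only
#' in the amplitude of one stated band. This emulates two cohorts whose
#' morphology differs at a single spatial scale.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param base list of arguments for [make_sinusoid_shell()] (R, folds, t,
#'   subdiv, waves).
#' @param band_delta list with `frequency` (must match a base band) and
#'   `delta` (additive amplitude change for group B, mm).
#' @param seed integer seed; subject seeds are derived from it.
#' @param amp_jitter_sd standard deviation of the log-normal amplitude jitter.
#' @return list of subject entries: `pair`, `group` ("A"/"B"), `id`.
#' @export
make_cohort <- function(n_per_group, base, band_delta = list(frequency = NA,
                                                             delta = 0),
                        seed, amp_jitter_sd = 0.05) {
  if (n_per_group < 2L) stop("need at least 2 subjects per group")
  if (missing(seed) || is.null(seed)) stop("make_cohort requires a seed")
  folds <- base$folds
  if (is.null(folds)) stop("base specification must include folds")
  ib <- NA_integer_
  if (!is.na(band_delta$frequency)) {
    ib <- match(band_delta$frequency, folds$frequency)
    if (is.na(ib)) stop("band_delta frequency does not match a base band")
    if (folds$amplitude[ib] + band_delta$delta < 0)
      stop("band_delta would make the band amplitude negative")
  }
  subject_seeds <- with_seed(as.integer(seed),
                             sample.int(.Machine$integer.max - 1, 2 * n_per_group))
  out <- vector("list", 2 * n_per_group)
  for (i in seq_len(2 * n_per_group)) {
    grp <- if (i <= n_per_group) "A" else "B"
    f <- folds
    jit <- with_seed(subject_seeds[i] %% 1000000L + 7L,
                     stats::rnorm(nrow(f), 0, amp_jitter_sd))
    f$amplitude <- f$amplitude * exp(jit)
    if (grp == "B" && !is.na(ib)) f$amplitude[ib] <- f$amplitude[ib] + band_delta$delta
    pair <- make_sinusoid_shell(
      R = base$R %||% 10, folds = f, t = base$t %||% 1,
      subdiv = base$subdiv %||% 4L, seed = subject_seeds[i],
      waves = base$waves %||% 6L)
    out[[i]] <- list(pair = pair, group = grp,
                     id = sprintf("%s%02d", grp,
                                  ((i - 1) %% n_per_group) + 1L))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
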