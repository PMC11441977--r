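#' Read a triangulated surface
#'
#' Reads FreeSurfer binary triangle surfaces, OFF, PLY (ascii and
#' binary-little-endian) and STL (ascii and binary). Coordinates are taken
#' as-is in mm (for FreeSurfer surfaces, the surface RAS coordinates; no
#' vox2ras transform is applied -- the coarse-graining method is
#' translation/rotation invariant). Orientation is repaired to consistent
#' outward winding on load, and degenerate faces are dropped with a warning.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"freesurfer"`, `"off"`, `"ply"`, `"stl"`.
#'   `"auto"` guesses from the file extension, falling back to content sniffing.
#' @param watertight require a closed 2-manifold surface (error if not).
#' @param repair repair winding/outward orientation automatically.
#' @param quiet suppress the orientation-repair message.
#' @return a validated `cs_mesh`.
#' @export
read_surface <- function(path, format = c("auto", "freesurfer", "off", "ply", "stl"),
                         watertight = TRUE, repair = TRUE, quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_surface_format(path)
  raw <- switch(format,
    freesurfer = read_fs_surface(path),
    off = read_off(path),
    ply = read_ply(path),
    stl = read_stl(path),
    stop("unknown surface format: ", format)
  )
  m <- mesh3(raw$vertices, raw$faces, name = basename(path))
  er <- mesh_edge_report(m)
  if (watertight && !er$watertight)
    stop(sprintf(
      "surface is not watertight: %d boundary edges, %d non-manifold edges",
      er$n_boundary_edges, er$n_nonmanifold_edges))
  if (repair) m <- orient_mesh(m, quiet = quiet)
  m
}

guess_surface_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("off", "ply", "stl")) return(ext)
  if (ext %in% c("pial", "white", "orig", "sphere", "inflated", "surf", ""))
    return("freesurfer")
  # content sniff
  head <- readBin(path, "raw", 16L)
  if (length(head) >= 3 && identical(as.integer(head[1:3]), c(255L, 255L, 254L)))
    return("freesurfer")
  txt <- rawToChar(head[head != as.raw(0)])
  if (grepl("^OFF", txt)) return("off")
  if (grepl("^ply", txt)) return("ply")
  if (grepl("^solid", txt)) return("stl")
  stop("cannot determine surface format of ", path)
}

# --- FreeSurfer binary triangle surface ------------------------------------
# magic 0xFFFFFE, creator string terminated by "\n\n", then big-endian
# int32 nvertices, int32 nfaces, float32 xyz triplets, int32 index triplets.
read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 3L, size = 1L, signed = FALSE)
  if (!identical(magic, c(255L, 255L, 254L)))
    stop("not a FreeSurfer binary triangle surface (bad magic)")
  # creator string: read bytes until two consecutive newlines
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop("truncated FreeSurfer surface header")
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (nv <= 0 || nf <= 0) stop("corrupt FreeSurfer surface counts")
  v <- readBin(con, "numeric", 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", 3L * nf, size = 4L, endian = "big")
  if (length(v) < 3L * nv || length(f) < 3L * nf)
    stop("truncated FreeSurfer surface data")
  list(vertices = matrix(v, ncol = 3, byrow = TRUE),
       faces = matrix(f, ncol = 3, byrow = TRUE) + 1L)
}

#' Write a FreeSurfer binary triangle surface
#' @param mesh a `cs_mesh`.
#' @param path output path.
#' @param creator creator comment embedded in the header.
#' @export
write_fs_surface <- function(mesh, path, creator = "created by cortexscale") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255L, 255L, 254L)), con)
  writeBin(charToRaw(paste0(creator, "\n\n")), con)
  writeBin(as.integer(nrow(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces - 1L)), con, size = 4L, endian = "big")
  invisible(path)
}

# --- OFF --------------------------------------------------------------------
read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!grepl("^OFF", lines[1])) stop("not an OFF file")
  lines <- lines[-1]
  counts <- scan(text = lines[1], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  body <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  v <- matrix(body[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  rest <- body[-seq_len(3 * nv)]
  faces <- matrix(NA_integer_, nf, 3)
  pos <- 1
  for (i in seq_len(nf)) {
    k <- rest[pos]
    if (k != 3) stop("only triangular OFF faces are supported")
    faces[i, ] <- rest[pos + 1:3] + 1L
    pos <- pos + k + 1
  }
  list(vertices = v, faces = faces)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

# --- PLY --------------------------------------------------------------------
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- read_bin_line(con)
    hdr <- c(hdr, ln)
    if (identical(ln, "end_header")) break
    if (length(hdr) > 200) stop("PLY header too long / corrupt")
  }
  if (!grepl("^ply", hdr[1])) stop("not a PLY file")
  fmt <- strsplit(trimws(hdr[grepl("^format", hdr)]), "\\s+")[[1]][2]
  nv <- nf <- 0L
  vprops <- character()
  cur <- ""
  for (ln in hdr) {
    w <- strsplit(trimws(ln), "\\s+")[[1]]
    if (w[1] == "element") {
      cur <- w[2]
      if (cur == "vertex") nv <- as.integer(w[3])
      if (cur == "face") nf <- as.integer(w[3])
    } else if (w[1] == "property" && cur == "vertex") {
      vprops <- c(vprops, paste(w[-1], collapse = " "))
    }
  }
  nprop <- length(vprops)
  ixyz <- match(c("x", "y", "z"), vapply(strsplit(vprops, " "), function(p) p[length(p)], ""))
  if (anyNA(ixyz)) stop("PLY vertex element lacks x/y/z")
  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    vv <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                   function(w) as.numeric(w[ixyz]), numeric(3)))
    faces <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      w <- as.integer(strsplit(trimws(body[nv + i]), "\\s+")[[1]])
      if (w[1] != 3) stop("only triangular PLY faces are supported")
      faces[i, ] <- w[2:4] + 1L
    }
    list(vertices = vv, faces = faces)
  } else if (fmt == "binary_little_endian") {
    sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
               char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
               short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
               int = 4L, int32 = 4L, uint = 4L, uint32 = 4L)
    ptypes <- vapply(strsplit(vprops, " "), `[`, "", 1L)
    psz <- sizes[ptypes]
    if (anyNA(psz)) stop("unsupported PLY vertex property type")
    stride <- sum(psz)
    vraw <- readBin(con, "raw", nv * stride)
    vv <- matrix(0, nv, 3)
    off <- cumsum(c(0L, psz))[seq_len(nprop)]
    for (d in 1:3) {
      p <- ixyz[d]
      sz <- psz[p]
      idx <- as.vector(outer(seq_len(sz), (seq_len(nv) - 1L) * stride + off[p], "+"))
      col <- readBin(vraw[idx], "numeric", nv, size = sz, endian = "little")
      vv[, d] <- col
    }
    faces <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      k <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
      if (k != 3) stop("only triangular PLY faces are supported")
      faces[i, ] <- readBin(con, "integer", 3L, size = 4L, endian = "little") + 1L
    }
    list(vertices = vv, faces = faces)
  } else stop("unsupported PLY format: ", fmt)
}

read_bin_line <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L || b == as.raw(10)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

# --- STL --------------------------------------------------------------------
# STL stores loose triangles; vertices are merged by exact coordinate match.
read_stl <- function(path) {
  head <- readBin(path, "raw", 6L)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    grepl("facet", paste(readLines(path, n = 20L, warn = FALSE), collapse = " "))
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  key <- apply(tri, 1, function(r) paste(format(r, digits = 15), collapse = ","))
  uid <- match(key, unique(key))
  vv <- tri[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = vv, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  xyz <- t(vapply(strsplit(trimws(vl), "\\s+"),
                  function(w) as.numeric(w[2:4]), numeric(3)))
  if (nrow(xyz) %% 3 != 0) stop("corrupt ascii STL")
  xyz
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (nf <= 0) stop("corrupt binary STL")
  out <- matrix(0, nf * 3L, 3L)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L)
    out[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  out
}

#' Write a triangulated surface
#' @param mesh a `cs_mesh`.
#' @param path output path.
#' @param format `"auto"` (from extension), `"off"`, `"ply"` (ascii) or
#'   `"freesurfer"`.
#' @export
write_surface <- function(mesh, path, format = c("auto", "off", "ply", "freesurfer")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("off", "ply")) ext else "freesurfer"
  }
  switch(format,
    off = write_off(mesh, path),
    ply = write_ply(mesh, path),
    freesurfer = write_fs_surface(mesh, path))
  invisible(path)
}

# --- surface pairs ----------------------------------------------------------

#' Pial/white surface pair
#'
#' The input unit of the cortical analysis: the outer (pial) and inner (white
#' matter) boundary of the cortical ribbon for one hemisphere. `white` may be
#' omitted ("single-surface mode", e.g. for solid non-brain objects), in which
#' case the ribbon is the full mesh interior.
#'
#' @param pial,white `cs_mesh` objects (white optional).
#' @param hemisphere free-text label.
#' @return a `cs_pair`.
#' @export
surface_pair <- function(pial, white = NULL, hemisphere = "") {
  stopifnot(inherits(pial, "cs_mesh"))
  if (!is.null(white)) stopifnot(inherits(white, "cs_mesh"))
  structure(list(pial = pial, white = white, hemisphere = hemisphere),
            class = "cs_pair")
}

#' @export
print.cs_pair <- function(x, ...) {
  cat(sprintf("<cs_pair%s: pial %d faces%s>\n",
              if (nzchar(x$hemisphere)) paste0(" ", x$hemisphere) else "",
              nrow(x$pial$faces),
              if (is.null(x$white)) ", single-surface mode"
              else sprintf(", white %d faces", nrow(x$white$faces))))
  invisible(x)
}

as_pair <- function(x) {
  if (inherits(x, "cs_pair")) return(x)
  if (inherits(x, "cs_mesh")) return(surface_pair(x))
  stop("expected a cs_pair or cs_mesh")
}

#' Validate a surface pair
#'
#' Checks watertightness and outward orientation of both meshes, that the
#' white surface volume is smaller than the pial volume, and containment of
#' the white surface inside the pial surface (every white vertex tested).
#' Failures are reported, not raised; only an empty mesh is a hard error.
#'
#' @param pair a `cs_pair` (or single `cs_mesh`).
#' @return a list report with per-check logicals and an overall `ok` flag.
#' @export
validate_pair <- function(pair) {
  pair <- as_pair(pair)
  if (is.null(pair$pial) || nrow(pair$pial$faces) == 0L) stop("empty pial mesh")
  rep_one <- function(m) {
    er <- mesh_edge_report(m)
    list(watertight = er$watertight, outward = mesh_volume(m) > 0,
         bbox = mesh_bbox(m))
  }
  out <- list(pial = rep_one(pair$pial))
  if (!is.null(pair$white)) {
    if (nrow(pair$white$faces) == 0L) stop("empty white mesh")
    out$white <- rep_one(pair$white)
    out$volume_order <- mesh_volume(pair$white, signed = FALSE) <
      mesh_volume(pair$pial, signed = FALSE)
    out$containment <- all(points_in_mesh(pair$white$vertices, pair$pial))
  }
  checks <- c(out$pial$watertight, out$pial$outward,
              if (!is.null(pair$white))
                c(out$white$watertight, out$white$outward,
                  out$volume_order, out$containment))
  out$ok <- all(checks)
  out
}

# --- occupancy grid I/O -----------------------------------------------------

#' Write / read an occupancy grid
#'
#' Grids can be stored as NIfTI-1 (uint8 occupancy; voxel spacing in pixdim,
#' origin in the qform translation) or as a plain-text JSON document holding
#' origin, spacing, shape and the occupancy as a run-length-encoded vector.
#' JSON round-trips are exact; NIfTI stores spacing/origin as float32.
#'
#' @param grid a `cs_grid` from [voxelise_ribbon()].
#' @param path output path.
#' @param format `"auto"` (from extension), `"nifti"` or `"json"`.
#' @export
write_grid <- function(grid, path, format = c("auto", "nifti", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("nii")) "nifti" else "json"
  }
  if (prod(dim(grid$occupancy)) == 0L) stop("empty grid")
  if (format == "nifti") {
    arr <- array(as.integer(grid$occupancy), dim = dim(grid$occupancy))
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, rep(grid$spacing, 3))
    xf <- diag(c(rep(grid$spacing, 3), 1))
    xf[1:3, 4] <- grid$origin + grid$spacing / 2  # voxel centres
    img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else {
    occ <- as.integer(grid$occupancy)
    r <- rle(occ)
    jsonlite::write_json(list(
      format = "cortexscale-grid", version = 1L,
      origin = grid$origin, spacing = grid$spacing, shape = dim(grid$occupancy),
      rle_lengths = r$lengths, rle_values = r$values
    ), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path, format = c("auto", "nifti", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("nii")) "nifti" else "json"
  }
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1]
    xf <- RNifti::xform(img)
    origin <- as.numeric(xf[1:3, 4]) - spacing / 2
    occ <- array(as.logical(as.array(img) > 0), dim = dim(img))
  } else {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(js$format, "cortexscale-grid")) stop("not a cortexscale grid file")
    spacing <- js$spacing
    origin <- as.numeric(js$origin)
    occ <- array(as.logical(inverse.rle(list(lengths = js$rle_lengths,
                                             values = js$rle_values))),
                 dim = js$shape)
  }
  new_grid(origin = origin, spacing = spacing, occupancy = occ)
}
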