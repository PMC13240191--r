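#' Triangle mesh container
#'
#' Minimal indexed triangle mesh: an `Nv x 3` matrix of coordinates and an
#' `Nf x 3` matrix of 1-based vertex indices.
#'
#' @param vertices Numeric `Nv x 3` matrix (columns x, y, z).
#' @param faces Integer `Nf x 3` matrix of vertex indices.
#' @return An object of class `mesh3d_lite`.
#' @export
mesh_3d <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (nrow(faces) && (any(faces < 1L) || any(faces > nrow(vertices))))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "mesh3d_lite")
}

#' @export
print.mesh3d_lite <- function(x, ...) {
  cat(sprintf("mesh: %d vertices, %d triangular faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

uint16_le <- function(v) {
  v <- as.integer(round(v))
  c(rbind(v %% 256L, v %/% 256L))
}

int16_le <- function(v) uint16_le(ifelse(v < 0, v + 65536L, v))

read_uint16_le <- function(bytes) bytes[c(TRUE, FALSE)] + 256L * bytes[c(FALSE, TRUE)]

read_int16_le <- function(bytes) {
  v <- read_uint16_le(bytes)
  ifelse(v >= 32768L, v - 65536L, v)
}

#' Serialize a mesh to bytes at fixed-point precision
#'
#' Layout: 5-byte header (vertex count and face count as little-endian
#' uint16, precision as one byte), then `3 * Nv` signed 16-bit fixed-point
#' coordinates (value * 2^precision), then `3 * Nf` unsigned 16-bit 0-based
#' vertex indices. Linear, uncompressed, and lossless at the declared
#' precision.
#'
#' @param mesh A [mesh_3d()].
#' @param precision Fractional bits of the fixed-point coordinates
#'   (default 8: resolution 1/256, range about +/-128).
#' @return Integer byte vector.
#' @export
serialize_mesh <- function(mesh, precision = 8L) {
  stopifnot(inherits(mesh, "mesh3d_lite"))
  precision <- as.integer(precision)
  q <- round(mesh$vertices * 2^precision)
  if (any(q < -32768 | q > 32767))
    stop("quantization error: coordinate out of 16-bit fixed-point range")
  c(uint16_le(nrow(mesh$vertices)), uint16_le(nrow(mesh$faces)), precision,
    if (nrow(mesh$vertices)) int16_le(as.integer(t(q))),
    if (nrow(mesh$faces)) uint16_le(as.integer(t(mesh$faces)) - 1L))
}

#' @rdname serialize_mesh
#' @param bytes Integer byte vector from `serialize_mesh`.
#' @export
deserialize_mesh <- function(bytes) {
  bytes <- as.integer(bytes)
  if (length(bytes) < 5L) stop("truncated mesh stream")
  nv <- read_uint16_le(bytes[1:2])
  nf <- read_uint16_le(bytes[3:4])
  precision <- bytes[5L]
  need <- 5L + 6L * nv + 6L * nf
  if (length(bytes) < need) stop("truncated mesh stream")
  off <- 5L
  verts <- if (nv) {
    q <- read_int16_le(bytes[(off + 1L):(off + 6L * nv)])
    matrix(q / 2^precision, ncol = 3L, byrow = TRUE)
  } else matrix(numeric(0), ncol = 3L)
  off <- off + 6L * nv
  faces <- if (nf) {
    matrix(read_uint16_le(bytes[(off + 1L):(off + 6L * nf)]) + 1L,
           ncol = 3L, byrow = TRUE)
  } else matrix(integer(0), ncol = 3L)
  mesh_3d(verts, faces)
}

#' Read and write the OBJ subset used for mesh fixtures
#'
#' Only `v x y z` and `f i j k` records (1-based indices) are handled.
#'
#' @param path File path.
#' @param mesh A [mesh_3d()].
#' @return `read_obj`: a [mesh_3d()].
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  parse3 <- function(x, fun) {
    t(vapply(strsplit(trimws(sub("^[vf] +", "", x)), " +"),
             function(p) fun(p[1:3]), fun(c("0", "0", "0"))))
  }
  verts <- if (length(vl)) parse3(vl, as.numeric) else matrix(numeric(0), ncol = 3)
  faces <- if (length(fl)) parse3(fl, as.integer) else matrix(integer(0), ncol = 3)
  mesh_3d(verts, faces)
}

#' @rdname read_obj
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh3d_lite"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(mesh$vertices))
    writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$faces))
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  invisible(path)
}
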