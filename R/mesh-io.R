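#' Mesh file I/O (ASCII PLY, OBJ, STL)
#'
#' `write_mesh_ply()`/`read_mesh_ply()` round-trip a [surface_mesh()]
#' through ASCII PLY; `write_mesh_obj()`/`read_mesh_obj()` through
#' Wavefront OBJ; `read_mesh_stl()` reads ASCII STL (read-only, vertices
#' are merged exactly). Coordinates are written with 9 significant digits
#' so identical meshes produce identical files.
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @return Writers return `path` invisibly; readers return a `surface_mesh`.
#' @name mesh_io
NULL

#' @rdname mesh_io
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  f <- mesh$faces - 1L
  hdr <- c("ply", "format ascii 1.0",
           "comment wssphantom surface mesh (mm)",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  vlines <- paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3]))
  flines <- paste(3L, f[, 1], f[, 2], f[, 3])
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop_config("not a PLY file: %s", path)
  if (!grepl("ascii", lines[2])) stop_config("only ASCII PLY is supported")
  end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  vdat <- utils::read.table(text = lines[(end + 1):(end + nv)])
  fdat <- utils::read.table(text = lines[(end + nv + 1):(end + nv + nf)])
  if (any(fdat[, 1] != 3L)) stop_config("only triangle PLY faces are supported")
  surface_mesh(unname(as.matrix(vdat[, 1:3])), unname(as.matrix(fdat[, 2:4])) + 1L)
}

#' @rdname mesh_io
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c("# wssphantom surface mesh (mm)",
             paste("v", fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])),
             paste("f", f[, 1], f[, 2], f[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_mesh_obj <- function(path) {
  lines <- readLines(path)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  v <- utils::read.table(text = vlines)[, 2:4]
  fidx <- lapply(strsplit(sub("^f ", "", flines), "\\s+"), function(p) {
    as.integer(vapply(strsplit(p, "/"), `[[`, "", 1L))
  })
  f <- do.call(rbind, fidx)
  if (ncol(f) != 3L) stop_config("only triangle OBJ faces are supported")
  surface_mesh(unname(as.matrix(v)), f)
}

#' @rdname mesh_io
#' @export
read_mesh_stl <- function(path) {
  lines <- trimws(readLines(path))
  if (!startsWith(lines[1], "solid")) stop_config("only ASCII STL is supported")
  vl <- lines[startsWith(lines, "vertex")]
  coords <- utils::read.table(text = vl)[, 2:4]
  coords <- as.matrix(coords)
  if (nrow(coords) %% 3L != 0L) stop_config("malformed STL: vertex count not a multiple of 3")
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  uid <- !duplicated(key)
  verts <- coords[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}
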