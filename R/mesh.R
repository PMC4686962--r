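#' Triangulated open-tube surface mesh
#'
#' A light container for a triangle mesh in right-handed Cartesian mm
#' coordinates: vertices, faces (1-based vertex triples with consistent
#' outward orientation), per-face areas, boundary loops (inlet, main
#' outlet, and side outlet for a bifurcation), and optional bookkeeping
#' attached by the generators (vertex group, structured-grid indices,
#' ostium-rim flags).
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param meta optional named list of generator bookkeeping.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, meta = list()) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop_config("vertices must be n x 3")
  if (nrow(faces) < 1L) stop_config("mesh has no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop_config("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces, meta = meta),
                 class = "surface_mesh")
  m$face_areas <- face_areas(m)
  if (any(m$face_areas <= 0))
    stop_config("mesh contains degenerate (zero-area) faces")
  m$boundary_loops <- boundary_loops(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d faces, area %.3f mm^2, %d boundary loop(s)\n",
              nrow(x$vertices), nrow(x$faces), sum(x$face_areas),
              length(x$boundary_loops)))
  invisible(x)
}

#' Per-face areas of a triangle mesh (mm^2)
#' @param mesh a [surface_mesh()] or a list with `vertices` and `faces`.
#' @return Numeric vector of face areas.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * vec_norm(cr)
}

#' Face centroids (mm)
#' @inheritParams face_areas
#' @return Numeric m x 3 matrix.
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Extract ordered boundary loops of an open mesh
#'
#' Boundary edges are those used by exactly one face. Each loop is returned
#' as an ordered closed sequence of vertex indices.
#'
#' @inheritParams face_areas
#' @return List of integer vectors, one per closed boundary loop, ordered
#'   by decreasing loop length.
#' @export
boundary_loops <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(key)
  open_key <- names(cnt)[cnt == 1L]
  if (length(open_key) == 0L) return(list())
  be <- edges[key %in% open_key, , drop = FALSE]
  # adjacency: each boundary vertex has exactly two boundary neighbours
  nbr <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  nbr <- lapply(nbr, unique)
  visited <- new.env(hash = TRUE)
  loops <- list()
  for (start in sort(unique(as.vector(be)))) {
    sk <- as.character(start)
    if (!is.null(visited[[sk]])) next
    loop <- integer(0)
    cur <- start
    prev <- NA_integer_
    repeat {
      loop <- c(loop, cur)
      visited[[as.character(cur)]] <- TRUE
      nx <- setdiff(nbr[[as.character(cur)]], prev)
      if (length(nx) == 0L) break
      prev <- cur
      cur <- nx[1L]
      if (cur == start) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops[order(-vapply(loops, length, 1L))]
}

#' Generate the triangulated phantom surface with its centerline
#'
#' Sweeps circular cross-sections of the ground-truth radius profile along a
#' straight main centerline, opens an ostium hole where the side-branch
#' cylinder meets the wall, and extrudes the side branch from the ostium rim
#' so the join is watertight. The result is an open tube with exactly three
#' boundary loops (inlet, main outlet, side outlet) and consistent outward
#' normals. Generation is fully deterministic.
#'
#' @param spec a [bifurcation_spec()].
#' @param resolution target edge length (mm); must be positive and smaller
#'   than the throat radius.
#' @param profile optionally a precomputed [radius_profile()] for the main
#'   branch (defaults to `build_radius_profile(spec)`); used to mesh
#'   perturbed geometries from measured radii.
#' @return List with elements `mesh` (a [surface_mesh()]) and `centerline`.
#' @examples
#' g <- generate_bifurcation_mesh(bifurcation_spec(), resolution = 0.4)
#' length(g$mesh$boundary_loops) # 3
#' @export
generate_bifurcation_mesh <- function(spec, resolution = 0.2, profile = NULL) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  a_throat <- spec$main$a_prox * sqrt(1 - spec$main$area_stenosis / 100)
  check_number(resolution, "resolution", lower = 0, strict_lower = TRUE)
  if (resolution >= a_throat)
    stop_config("resolution %g mm too coarse to resolve the %g mm throat radius",
                resolution, a_throat)
  profile <- profile %||% build_radius_profile(spec, ds = resolution / 2)
  m <- spec$main
  cl <- straight_centerline(m$length, ds = resolution)
  n_ax <- max(4L, as.integer(round(m$length / resolution)))
  n_th <- max(12L, as.integer(ceiling(2 * pi * max(profile$a) / resolution)))
  s_ring <- seq(0, m$length, length.out = n_ax + 1L)
  a_ring <- stats::approx(profile$s, profile$a, xout = s_ring, rule = 2)$y
  theta <- 2 * pi * (seq_len(n_th) - 1L) / n_th
  # vertex grid: ring-major, theta = 0 on +x (towards the ostium)
  vx <- as.vector(outer(a_ring, cos(theta)))
  vy <- as.vector(outer(a_ring, sin(theta)))
  vz <- as.vector(outer(s_ring, rep(1, n_th)))
  verts <- cbind(vx, vy, vz)
  vid <- function(i, j) (j - 1L) * (n_ax + 1L) + i  # i = ring 1..n_ax+1, j = sector 1..n_th
  faces <- matrix(0L, 0L, 3L)
  i <- rep(seq_len(n_ax), n_th)
  j <- rep(seq_len(n_th), each = n_ax)
  jp <- ifelse(j == n_th, 1L, j + 1L)
  # outward orientation for CCW theta and +z axis
  f1 <- cbind(vid(i, j), vid(i, jp), vid(i + 1L, j))
  f2 <- cbind(vid(i + 1L, j), vid(i, jp), vid(i + 1L, jp))
  faces <- rbind(f1, f2)

  # side branch axis in the x-z plane
  phi <- spec$side$angle * pi / 180
  d_axis <- c(sin(phi), 0, cos(phi))
  p0 <- c(0, 0, spec$side$ostium_s)
  r_side <- spec$side$radius

  inside_branch <- function(p) {
    rel <- sweep(p, 2, p0)
    t <- rel %*% d_axis
    rad2 <- rowSums(rel^2) - t^2
    (t > 0) & (rad2 < r_side^2)
  }
  cent <- (verts[faces[, 1], ] + verts[faces[, 2], ] + verts[faces[, 3], ]) / 3
  drop_face <- inside_branch(cent)
  if (!any(drop_face))
    stop_config("side branch does not intersect the main-branch wall; check ostium position and radius")
  keep_faces <- faces[!drop_face, , drop = FALSE]

  # ostium rim: boundary loop of the kept main surface that is not an end ring
  tmp <- list(vertices = verts, faces = keep_faces)
  loops <- boundary_loops(tmp)
  is_end <- vapply(loops, function(lp) {
    z <- verts[lp, 3]
    all(abs(z) < 1e-9) || all(abs(z - m$length) < 1e-9)
  }, logical(1))
  rim_loops <- loops[!is_end]
  if (length(rim_loops) != 1L)
    stop_config("self-intersecting branch configuration: ostium hole is not a single loop")
  rim <- rim_loops[[1L]]

  # orient the rim loop by increasing angle around the branch axis
  u_ref <- c(cos(phi), 0, -sin(phi))   # perpendicular to d_axis in the x-z plane
  w_ref <- c(d_axis[2] * u_ref[3] - d_axis[3] * u_ref[2],
             d_axis[3] * u_ref[1] - d_axis[1] * u_ref[3],
             d_axis[1] * u_ref[2] - d_axis[2] * u_ref[1])
  rel <- sweep(verts[rim, , drop = FALSE], 2, p0)
  psi <- atan2(rel %*% w_ref, rel %*% u_ref)
  # the walked loop is already ordered; flip if psi decreases on average
  dpsi <- wrap_angle(diff(c(psi, psi[1])))
  if (sum(dpsi) < 0) {
    rim <- rev(rim)
    rel <- sweep(verts[rim, , drop = FALSE], 2, p0)
    psi <- atan2(rel %*% w_ref, rel %*% u_ref)
  }
  n_rim <- length(rim)
  t_rim <- as.vector(rel %*% d_axis)

  # strictly monotone end-ring angles along the loop: raw rim angles can
  # repeat (two grid vertices projecting to the same angle), which would
  # collapse end-ring triangles
  psi <- as.vector(psi)
  steps <- pmax(wrap_angle(diff(c(psi, psi[1]))), 1e-3)
  steps <- steps * (2 * pi / sum(steps))
  psi_mono <- psi[1] + cumsum(c(0, steps[-length(steps)]))

  # extrude the branch: blend each rim vertex to a circle of radius r_side
  L_b <- spec$side$length
  t_end <- L_b
  if (max(t_rim) >= t_end)
    stop_config("side branch too short for its own ostium footprint")
  end_ring <- sweep(r_side * (cos(psi_mono) %*% t(u_ref) + sin(psi_mono) %*% t(w_ref)) +
                      t_end * matrix(d_axis, n_rim, 3, byrow = TRUE), 2, p0, "+")
  n_b <- max(2L, as.integer(round((L_b - max(t_rim)) / resolution)))
  branch_vids <- matrix(0L, n_b + 1L, n_rim)
  branch_vids[1L, ] <- rim
  new_verts <- list()
  next_id <- nrow(verts)
  rim_xyz <- verts[rim, , drop = FALSE]
  for (k in seq_len(n_b)) {
    f <- k / n_b
    # smoothstep blend: keeps the first ring close to the rim shape
    fb <- f * f * (3 - 2 * f)
    ring <- (1 - fb) * rim_xyz + fb * end_ring
    new_verts[[k]] <- ring
    branch_vids[k + 1L, ] <- next_id + seq_len(n_rim)
    next_id <- next_id + n_rim
  }
  verts_all <- rbind(verts, do.call(rbind, new_verts))
  bf <- list()
  for (k in seq_len(n_b)) {
    aa <- branch_vids[k, ]
    bb <- branch_vids[k + 1L, ]
    jn <- c(seq(2, n_rim), 1L)
    bf[[k]] <- rbind(cbind(aa, aa[jn], bb), cbind(bb, aa[jn], bb[jn]))
  }
  branch_faces <- do.call(rbind, bf)
  faces_all <- rbind(keep_faces, branch_faces)

  # drop unreferenced vertices (interior of the ostium hole), reindex
  used <- sort(unique(as.vector(faces_all)))
  remap <- integer(nrow(verts_all))
  remap[used] <- seq_along(used)
  faces_all <- matrix(remap[faces_all], ncol = 3)
  vgrid <- cbind(ring = rep(seq_len(n_ax + 1L), n_th),
                 sector = rep(seq_len(n_th), each = n_ax + 1L))
  vgrid <- rbind(vgrid, matrix(NA_integer_, nrow(verts_all) - nrow(verts), 2,
                               dimnames = list(NULL, c("ring", "sector"))))
  group <- c(rep("main", nrow(verts)), rep("side", nrow(verts_all) - nrow(verts)))
  group[rim] <- "rim"
  verts_used <- verts_all[used, , drop = FALSE]
  group <- group[used]
  vgrid <- vgrid[used, , drop = FALSE]

  face_group <- ifelse(seq_len(nrow(faces_all)) <= nrow(keep_faces), "main", "side")
  rim_new <- remap[rim]
  touches_rim <- matrix(faces_all %in% rim_new, ncol = 3)
  ostium_rim_face <- rowSums(touches_rim) > 0

  mesh <- surface_mesh(verts_used, faces_all, meta = list(
    spec = spec, resolution = resolution,
    n_ax = n_ax, n_th = n_th, s_ring = s_ring, a_ring = a_ring,
    vertex_group = group, vgrid = vgrid,
    face_group = face_group, ostium_rim_face = ostium_rim_face,
    branch_axis = d_axis, branch_origin = p0, rim_vertices = rim_new,
    branch_vertex_start = match("side", group)))
  if (length(mesh$boundary_loops) != 3L)
    stop_config("generated bifurcation mesh does not have 3 boundary loops")
  list(mesh = mesh, centerline = cl)
}

#' Generate a plain straight-tube mesh (no side branch)
#'
#' Utility for validation and fixtures: a swept circular tube of the given
#' radius profile (or constant radius) with two boundary loops.
#'
#' @param length tube length (mm).
#' @param radius constant radius (mm), ignored when `profile` is given.
#' @param resolution target edge length (mm).
#' @param profile optional [radius_profile()].
#' @return List with `mesh` and `centerline`.
#' @export
generate_tube_mesh <- function(length, radius = 1.25, resolution = 0.2,
                               profile = NULL) {
  check_number(length, "length", lower = 0, strict_lower = TRUE)
  check_number(resolution, "resolution", lower = 0, strict_lower = TRUE)
  cl <- straight_centerline(length, ds = resolution)
  n_ax <- max(4L, as.integer(round(length / resolution)))
  s_ring <- seq(0, length, length.out = n_ax + 1L)
  if (is.null(profile)) {
    a_ring <- rep(radius, n_ax + 1L)
  } else {
    a_ring <- stats::approx(profile$s, profile$a, xout = s_ring, rule = 2)$y
  }
  n_th <- max(12L, as.integer(ceiling(2 * pi * max(a_ring) / resolution)))
  theta <- 2 * pi * (seq_len(n_th) - 1L) / n_th
  verts <- cbind(as.vector(outer(a_ring, cos(theta))),
                 as.vector(outer(a_ring, sin(theta))),
                 as.vector(outer(s_ring, rep(1, n_th))))
  vid <- function(i, j) (j - 1L) * (n_ax + 1L) + i
  i <- rep(seq_len(n_ax), n_th)
  j <- rep(seq_len(n_th), each = n_ax)
  jp <- ifelse(j == n_th, 1L, j + 1L)
  faces <- rbind(cbind(vid(i, j), vid(i, jp), vid(i + 1L, j)),
                 cbind(vid(i + 1L, j), vid(i, jp), vid(i + 1L, jp)))
  vgrid <- cbind(ring = rep(seq_len(n_ax + 1L), n_th),
                 sector = rep(seq_len(n_th), each = n_ax + 1L))
  mesh <- surface_mesh(verts, faces, meta = list(
    resolution = resolution, n_ax = n_ax, n_th = n_th,
    s_ring = s_ring, a_ring = a_ring,
    vertex_group = rep("main", nrow(verts)), vgrid = vgrid,
    face_group = rep("main", nrow(faces)),
    ostium_rim_face = rep(FALSE, nrow(faces))))
  list(mesh = mesh, centerline = cl)
}
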