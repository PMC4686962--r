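#' Reader-error perturbation parameters
#'
#' Segmentation by a human reader leaves smooth, spatially correlated errors
#' on the reconstructed lumen wall, typically below 0.1 mm in mean absolute
#' radius difference, plus a slight offset of the side-branch angle. The
#' perturbation model draws a Gaussian random field on the (arclength,
#' circumference) surface parameterization, smooths it to the requested
#' correlation length, rescales it so the realized mean |delta r| equals
#' `radial_sd` exactly, and applies it along the local radial direction.
#'
#' @param radial_sd target mean absolute radial error (mm). Default 0.08 mm,
#'   the scale of reported reader errors.
#' @param correlation_length smoothness of the error field (mm) along both
#'   surface directions. Default 2 mm, so errors look like hand-drawn
#'   contour deviations rather than pixel noise.
#' @param branch_angle_offset rotation applied to the side branch (deg).
#' @param seed integer RNG seed; the same seed reproduces the perturbation
#'   bit for bit.
#' @return An object of class `perturbation_params`.
#' @export
perturbation_params <- function(radial_sd = 0.08, correlation_length = 2,
                                branch_angle_offset = 0, seed = 1L) {
  check_number(radial_sd, "radial_sd", lower = 0)
  check_number(correlation_length, "correlation_length", lower = 0,
               strict_lower = TRUE)
  check_number(branch_angle_offset, "branch_angle_offset")
  check_number(seed, "seed")
  structure(list(radial_sd = radial_sd,
                 correlation_length = correlation_length,
                 branch_angle_offset = branch_angle_offset,
                 seed = as.integer(seed)),
            class = "perturbation_params")
}

# smooth correlated field on the structured (ring, sector) grid,
# rescaled so mean(|field|) == radial_sd exactly
correlated_radial_field <- function(s_ring, a_ring, n_th, params) {
  n_ax <- length(s_ring)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  z <- matrix(stats::rnorm(n_ax * n_th), n_ax, n_th)
  lc <- params$correlation_length
  # Gaussian smoothing kernels: axial (open) and circumferential (periodic),
  # normalized to unit output variance per row so the smoothed field is
  # stationary along the vessel (row-sum normalization would inflate the
  # variance at the two ends, biasing the proximal segment)
  ks <- outer(s_ring, s_ring, function(x, y) exp(-((x - y)^2) / (2 * lc^2)))
  ks <- ks / sqrt(rowSums(ks^2))
  circ <- 2 * pi * mean(a_ring)
  darc <- circ / n_th
  idx <- seq_len(n_th) - 1L
  dist_th <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    pmin(d, n_th - d) * darc
  })
  kt <- exp(-dist_th^2 / (2 * lc^2))
  kt <- kt / sqrt(rowSums(kt^2))
  f <- ks %*% z %*% t(kt)
  # normalize on ring-averaged radii: <|delta r|> is defined on per-ring
  # radius differences, the way reconstructed radius profiles are compared
  mu <- mean(abs(rowMeans(f)))
  if (mu < .Machine$double.eps) return(matrix(0, n_ax, n_th))
  f * (params$radial_sd / mu)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Emulate a reader reconstruction of a phantom mesh
#'
#' Applies a seeded, smoothly correlated radial error field to the main
#' branch wall and rotates the side branch by the configured angular offset
#' about the ostium. The same seed yields a bitwise-identical mesh. With
#' `radial_sd = 0` and zero angle offset the input is returned unchanged.
#'
#' @param geometry the list returned by [generate_bifurcation_mesh()] or
#'   [generate_tube_mesh()] (fields `mesh` and `centerline`).
#' @param params a [perturbation_params()].
#' @return A list with `mesh`, `centerline`, `radial_field` (the applied
#'   per-(ring, sector) radial error, mm) and `params`.
#' @examples
#' g <- generate_tube_mesh(9, resolution = 0.5)
#' p <- perturb_reconstruction(g, perturbation_params(radial_sd = 0.05, seed = 7))
#' @export
perturb_reconstruction <- function(geometry, params) {
  stopifnot(inherits(params, "perturbation_params"))
  mesh <- geometry$mesh
  stopifnot(inherits(mesh, "surface_mesh"))
  meta <- mesh$meta
  if (is.null(meta$vgrid))
    stop_config("mesh lacks structured-grid metadata; only generated meshes can be perturbed")
  a_min <- min(meta$a_ring)
  if (params$radial_sd >= a_min)
    stop_config("radial_sd %g mm would close the %g mm lumen throat",
                params$radial_sd, a_min)
  if (params$radial_sd == 0 && params$branch_angle_offset == 0) {
    return(list(mesh = mesh, centerline = geometry$centerline,
                radial_field = matrix(0, length(meta$s_ring), meta$n_th),
                params = params))
  }
  f <- correlated_radial_field(meta$s_ring, meta$a_ring, meta$n_th, params)
  verts <- mesh$vertices
  grid <- meta$vgrid
  on_grid <- !is.na(grid[, "ring"])
  ring <- grid[on_grid, "ring"]
  sector <- grid[on_grid, "sector"]
  dr <- f[cbind(ring, sector)]
  a0 <- meta$a_ring[ring]
  # a reconstruction of a patent lumen never closes it: floor rare extreme
  # excursions at 20% of the local radius
  dr <- pmax(dr, -0.8 * a0)
  scale <- (a0 + dr) / a0
  # radial displacement about the straight main axis (z)
  verts[on_grid, 1] <- verts[on_grid, 1] * scale
  verts[on_grid, 2] <- verts[on_grid, 2] * scale
  # side-branch angular offset: rigid rotation about the ostium pivot (y axis)
  if (!is.null(meta$branch_origin) && params$branch_angle_offset != 0) {
    off <- params$branch_angle_offset * pi / 180
    side <- !on_grid
    if (any(side)) {
      rel <- sweep(verts[side, , drop = FALSE], 2, meta$branch_origin)
      rot <- cbind(rel[, 1] * cos(off) + rel[, 3] * sin(off),
                   rel[, 2],
                   -rel[, 1] * sin(off) + rel[, 3] * cos(off))
      verts[side, ] <- sweep(rot, 2, meta$branch_origin, "+")
    }
  }
  meta$a_ring_measured <- meta$a_ring + rowMeans(f)
  out <- surface_mesh(verts, mesh$faces, meta = meta)
  list(mesh = out, centerline = geometry$centerline, radial_field = f,
       params = params)
}

#' Measure the main-branch radius profile of a (possibly perturbed) mesh
#'
#' Per structured ring, the radius is the mean distance of the surviving
#' ring vertices to the main centerline axis. Segment labels are copied
#' from a reference profile (regions are defined on the ground-truth
#' phantom geometry).
#'
#' @param mesh a generated or perturbed [surface_mesh()].
#' @param reference optional [radius_profile()] providing segment labels.
#' @return A [radius_profile()] sampled at the mesh ring positions.
#' @export
measured_radius_profile <- function(mesh, reference = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  meta <- mesh$meta
  if (is.null(meta$vgrid)) stop_config("mesh lacks structured-grid metadata")
  grid <- meta$vgrid
  on_grid <- !is.na(grid[, "ring"])
  r <- sqrt(mesh$vertices[on_grid, 1]^2 + mesh$vertices[on_grid, 2]^2)
  a <- as.numeric(tapply(r, grid[on_grid, "ring"], mean))
  s <- meta$s_ring[sort(unique(grid[on_grid, "ring"]))]
  seg <- NULL
  if (!is.null(reference)) {
    idx <- vapply(s, function(si) which.min(abs(reference$s - si)), 1L)
    seg <- as.character(reference$segment[idx])
  }
  radius_profile(s, a, seg)
}
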