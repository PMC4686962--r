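#' Per-face scalar field on a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param values numeric per-face values.
#' @param valid logical per-face validity mask.
#' @param units unit string (`"Pa"` for WSS/TAWSS, `""` for OSI).
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(mesh, values, valid = NULL, units = "Pa") {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (length(values) != nrow(mesh$faces))
    stop_config("field length does not match the face count")
  valid <- valid %||% rep(TRUE, length(values))
  if (any(!is.finite(values[valid])))
    stop_config("scalar field must be finite on valid faces")
  structure(list(mesh = mesh, values = as.numeric(values), valid = valid,
                 units = units), class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("Scalar field [%s]: %d faces (%d valid), range %.4g-%.4g\n",
              x$units, length(x$values), sum(x$valid), min(v), max(v)))
  invisible(x)
}

# periodic trapezoidal time integral over one cycle; on the uniform periodic
# grid this is dt * sum over samples
periodic_integral <- function(mat, dt) {
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  rowSums(mat) * dt
}

#' Time-averaged wall shear stress magnitude (TAWSS)
#'
#' `TAWSS = 1/T * integral over one cycle of |tau|`, with trapezoidal
#' integration on the uniform periodic time grid. A single-sample (steady)
#' series returns its magnitude unchanged.
#'
#' @param series a [wss_series()].
#' @return A [scalar_field()] in Pa.
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  mags <- sqrt(series$wss[, 1, , drop = FALSE]^2 +
               series$wss[, 2, , drop = FALSE]^2 +
               series$wss[, 3, , drop = FALSE]^2)
  mags <- matrix(mags, nrow = dim(series$wss)[1])
  vals <- periodic_integral(mags, series$dt) / series$T
  scalar_field(series$mesh, vals, valid = series$valid, units = "Pa")
}

#' Steady WSS magnitude of a single-sample series
#' @param series a [wss_series()] with `n_steps = 1`.
#' @return A [scalar_field()] in Pa.
#' @export
wss_magnitude <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  if (series$n_steps != 1L)
    stop_config("wss_magnitude expects a steady (single-step) series; use tawss()")
  tawss(series)
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 0.5 * (1 - |integral of tau dt| / integral of |tau| dt)`,
#' clipped to `[0, 0.5]` after a floating-point guard. Faces whose WSS is
#' identically zero over the cycle have no oscillation and get OSI 0.
#'
#' @param series a [wss_series()] with at least 2 time samples.
#' @return A dimensionless [scalar_field()] in `[0, 0.5]`.
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  if (series$n_steps < 2L) stop_config("OSI needs at least 2 time samples")
  nf <- dim(series$wss)[1]
  ix <- periodic_integral(matrix(series$wss[, 1, ], nrow = nf), series$dt)
  iy <- periodic_integral(matrix(series$wss[, 2, ], nrow = nf), series$dt)
  iz <- periodic_integral(matrix(series$wss[, 3, ], nrow = nf), series$dt)
  mags <- sqrt(series$wss[, 1, ]^2 + series$wss[, 2, ]^2 + series$wss[, 3, ]^2)
  imag <- periodic_integral(matrix(mags, nrow = nf), series$dt)
  num <- sqrt(ix^2 + iy^2 + iz^2)
  vals <- ifelse(imag <= .Machine$double.eps, 0, 0.5 * (1 - num / imag))
  vals <- pmin(pmax(vals, 0), 0.5)
  scalar_field(series$mesh, vals, valid = series$valid, units = "")
}

#' Low-WSS mask at a threshold
#'
#' Marks valid faces with `value < threshold` (strict inequality) and
#' reports the area-weighted fraction of masked wall.
#'
#' @param field a [scalar_field()] (Pa).
#' @param threshold low-WSS cut-off (Pa); default 0.5 Pa, the conventional
#'   at-risk threshold.
#' @return An object of class `low_wss_mask` with fields `mask`,
#'   `threshold`, `area` (mm^2) and `area_fraction`.
#' @export
low_wss_mask <- function(field, threshold = 0.5) {
  stopifnot(inherits(field, "scalar_field"))
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  areas <- field$mesh$face_areas
  mask <- field$valid & (field$values < threshold)
  valid_area <- sum(areas[field$valid])
  structure(list(mask = mask, threshold = threshold,
                 area = sum(areas[mask]),
                 area_fraction = sum(areas[mask]) / valid_area,
                 face_areas = areas, valid = field$valid),
            class = "low_wss_mask")
}

#' @export
print.low_wss_mask <- function(x, ...) {
  cat(sprintf("Low-WSS mask (< %g Pa): %.2f mm^2, %.1f%% of valid wall\n",
              x$threshold, x$area, 100 * x$area_fraction))
  invisible(x)
}

#' Dice similarity index between two low-WSS regions
#'
#' `SI = 2 * area(A and B) / (area(A) + area(B))`, area-weighted. The two
#' masks must live on the same mesh (same face count); to compare masks
#' across two different geometries, derive them from clip-aligned 2D maps
#' with [map_low_mask()] and [similarity_index_map()]. When both masks are
#' empty the SI is defined as 1 (perfect agreement of "nothing") and the
#' result carries attribute `both_empty`.
#'
#' @param maskA,maskB [low_wss_mask()] objects on the same mesh.
#' @return Dice coefficient in `[0, 1]`.
#' @export
similarity_index <- function(maskA, maskB) {
  stopifnot(inherits(maskA, "low_wss_mask"), inherits(maskB, "low_wss_mask"))
  if (length(maskA$mask) != length(maskB$mask))
    stop_config("masks live on incompatible supports")
  areas <- maskA$face_areas
  aA <- sum(areas[maskA$mask])
  aB <- sum(areas[maskB$mask])
  if (aA + aB == 0) return(structure(1, both_empty = TRUE))
  2 * sum(areas[maskA$mask & maskB$mask]) / (aA + aB)
}
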