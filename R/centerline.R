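#' Centerline with parallel-transported orthonormal frames
#'
#' A centerline is an ordered 3D polyline with cumulative arclength and a
#' per-point orthonormal frame (tangent, reference normal, binormal). The
#' reference normal is parallel-transported along the curve so that it
#' varies continuously and carries no axial twist; the circumferential
#' coordinate used for 2D unwrapping is measured from it.
#'
#' @param points numeric matrix (n x 3) of ordered coordinates (mm).
#' @param normal0 reference normal at the first point; must not be parallel
#'   to the initial tangent. Defaults to the unit x axis (projected).
#' @return An object of class `centerline` with fields `points`, `s`,
#'   `tangent`, `normal`, `binormal` (all n x 3 except `s`).
#' @export
centerline <- function(points, normal0 = c(1, 0, 0)) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop_config("centerline needs an n x 3 matrix with n >= 2")
  seg <- diff(points)
  len <- vec_norm(seg)
  if (any(len <= 0)) stop_config("centerline points must be distinct and ordered")
  s <- c(0, cumsum(len))
  n <- nrow(points)
  tangent <- matrix(0, n, 3)
  tangent[1, ] <- seg[1, ] / len[1]
  if (n > 2L) {
    mids <- unit_rows(seg[-1, , drop = FALSE] / len[-1] +
                      seg[-nrow(seg), , drop = FALSE] / len[-length(len)])
    tangent[2:(n - 1), ] <- mids
  }
  tangent[n, ] <- seg[n - 1, ] / len[n - 1]
  # parallel transport of the reference normal along the discrete curve
  normal <- matrix(0, n, 3)
  n0 <- normal0 - sum(normal0 * tangent[1, ]) * tangent[1, ]
  if (sqrt(sum(n0^2)) < 1e-9)
    stop_config("normal0 is parallel to the initial tangent")
  normal[1, ] <- n0 / sqrt(sum(n0^2))
  for (i in seq_len(n - 1L)) {
    t0 <- tangent[i, ]; t1 <- tangent[i + 1L, ]
    axis <- c(t0[2] * t1[3] - t0[3] * t1[2],
              t0[3] * t1[1] - t0[1] * t1[3],
              t0[1] * t1[2] - t0[2] * t1[1])
    sa <- sqrt(sum(axis^2))
    if (sa < 1e-12) {
      normal[i + 1L, ] <- normal[i, ]
    } else {
      axis <- axis / sa
      ca <- max(-1, min(1, sum(t0 * t1)))
      ang <- atan2(sa, ca)
      v <- normal[i, ]
      normal[i + 1L, ] <- v * cos(ang) +
        c(axis[2] * v[3] - axis[3] * v[2],
          axis[3] * v[1] - axis[1] * v[3],
          axis[1] * v[2] - axis[2] * v[1]) * sin(ang) +
        axis * sum(axis * v) * (1 - cos(ang))
    }
    # re-orthogonalize against accumulated drift
    nn <- normal[i + 1L, ] - sum(normal[i + 1L, ] * t1) * t1
    normal[i + 1L, ] <- nn / sqrt(sum(nn^2))
  }
  binormal <- cbind(tangent[, 2] * normal[, 3] - tangent[, 3] * normal[, 2],
                    tangent[, 3] * normal[, 1] - tangent[, 1] * normal[, 3],
                    tangent[, 1] * normal[, 2] - tangent[, 2] * normal[, 1])
  structure(list(points = points, s = s, tangent = tangent,
                 normal = normal, binormal = binormal),
            class = "centerline")
}

#' Straight main-branch centerline along the z axis
#'
#' The phantom layout is planar with a straight main branch; the side branch
#' leaves the main axis in the x-z plane, so the reference normal (+x)
#' points at the ostium and the circumferential origin is ostium-aligned.
#'
#' @param length branch length (mm).
#' @param ds point spacing (mm).
#' @return A [centerline()].
#' @export
straight_centerline <- function(length, ds = 0.5) {
  s <- seq(0, length, by = ds)
  if (s[length(s)] < length) s <- c(s, length)
  centerline(cbind(0, 0, s))
}

#' Interpolate centerline frames at arbitrary arclengths
#'
#' @param cl a [centerline()].
#' @param s arclength values (mm), clamped to the curve extent.
#' @return List of matrices `point`, `tangent`, `normal`, `binormal`.
#' @keywords internal
centerline_frame_at <- function(cl, s) {
  s <- pmin(pmax(s, cl$s[1]), cl$s[length(cl$s)])
  interp <- function(m) apply(m, 2, function(col) stats::approx(cl$s, col, xout = s)$y)
  pt <- interp(cl$points)
  if (is.null(dim(pt))) pt <- matrix(pt, nrow = 1)
  tg <- unit_rows(matrix(interp(cl$tangent), ncol = 3))
  nm <- matrix(interp(cl$normal), ncol = 3)
  nm <- unit_rows(nm - rowSums(nm * tg) * tg)
  bn <- cbind(tg[, 2] * nm[, 3] - tg[, 3] * nm[, 2],
              tg[, 3] * nm[, 1] - tg[, 1] * nm[, 3],
              tg[, 1] * nm[, 2] - tg[, 2] * nm[, 1])
  list(point = pt, tangent = tg, normal = nm, binormal = bn)
}

#' Write or read a centerline as CSV
#'
#' Columns: `s_mm, x, y, z, tx, ty, tz, nx, ny, nz`.
#' @param cl a [centerline()].
#' @param path file path.
#' @export
write_centerline_csv <- function(cl, path) {
  df <- data.frame(s_mm = cl$s,
                   x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3],
                   tx = cl$tangent[, 1], ty = cl$tangent[, 2], tz = cl$tangent[, 3],
                   nx = cl$normal[, 1], ny = cl$normal[, 2], nz = cl$normal[, 3])
  write_table_fixed(df, path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  df <- utils::read.csv(path)
  cl <- centerline(as.matrix(df[, c("x", "y", "z")]),
                   normal0 = c(df$nx[1], df$ny[1], df$nz[1]))
  cl
}
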