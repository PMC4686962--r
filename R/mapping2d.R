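#' Axial-by-circumferential bin grid on the main-branch wall
#'
#' Unwraps the main-branch wall into the standard 2D comparison grid:
#' planes perpendicular to the centerline every `ds` mm define axial rows,
#' each subdivided into `360/dtheta` angular bins. Faces are assigned by
#' their centroid's arclength projection and angle in the
#' parallel-transported frame; the circumferential origin (theta = 0) is
#' the direction from the centerline to the side-branch ostium, so maps of
#' a phantom and its reconstructions are directly comparable. Side-branch
#' faces and faces on the ostium rim are not mapped; bins left without any
#' face (the ostium hole) are invalid.
#'
#' @param mesh a [surface_mesh()] from the generators.
#' @param cl the matching [centerline()].
#' @param ds axial bin size (mm); default 0.45 mm.
#' @param dtheta angular bin size (deg); must divide 360; default 22.5
#'   (16 bins).
#' @param regions optional [detect_regions()] result labeling axial rows;
#'   regions are defined on the ground-truth phantom profile.
#' @return An object of class `bin_grid`.
#' @examples
#' g <- generate_tube_mesh(9, resolution = 0.45)
#' grid <- build_bin_grid(g$mesh, g$centerline)
#' grid$n_axial # 20 rows
#' @export
build_bin_grid <- function(mesh, cl, ds = 0.45, dtheta = 22.5, regions = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(cl, "centerline"))
  check_number(ds, "ds", lower = 0, strict_lower = TRUE)
  check_number(dtheta, "dtheta", lower = 0, strict_lower = TRUE)
  if (abs(360 / dtheta - round(360 / dtheta)) > 1e-9)
    stop_config("dtheta = %g does not divide 360 degrees", dtheta)
  n_theta <- as.integer(round(360 / dtheta))
  meta <- mesh$meta
  face_group <- meta$face_group %||% rep("main", nrow(mesh$faces))
  rim_face <- meta$ostium_rim_face %||% rep(FALSE, nrow(mesh$faces))
  mappable <- face_group == "main" & !rim_face
  cent <- face_centroids(mesh)

  # arclength projection and frame angle of each mappable face centroid
  L <- cl$s[length(cl$s)]
  s_face <- pmin(pmax(cent[, 3], 0), L)
  fr <- centerline_frame_at(cl, s_face)
  rel <- cent - fr$point
  theta0 <- 0
  if (!is.null(meta$branch_origin)) {
    # ostium direction at its axial station, expressed in the frame
    fo <- centerline_frame_at(cl, meta$branch_origin[3])
    od <- meta$branch_axis - sum(meta$branch_axis * fo$tangent[1, ]) * fo$tangent[1, ]
    theta0 <- atan2(sum(od * fo$binormal[1, ]), sum(od * fo$normal[1, ]))
  }
  theta <- atan2(rowSums(rel * fr$binormal), rowSums(rel * fr$normal)) - theta0
  theta <- theta %% (2 * pi)

  n_axial <- as.integer(floor(L / ds + 1e-9))
  if (n_axial < 1L) stop_config("branch shorter than one axial bin")
  row <- ifelse(mappable, pmin(floor(s_face / ds) + 1L, n_axial + 1L), NA_integer_)
  row[!is.na(row) & row > n_axial] <- NA_integer_  # tail shorter than ds dropped
  col <- ifelse(mappable, floor(theta / (dtheta * pi / 180)) + 1L, NA_integer_)
  col[!is.na(col) & col > n_theta] <- n_theta

  # measured mean wall radius per row (used for throat registration)
  r_face <- vec_norm(rel)
  ok <- !is.na(row)
  row_radius <- rep(NA_real_, n_axial)
  agg <- tapply(r_face[ok] * mesh$face_areas[ok], row[ok], sum)
  aw <- tapply(mesh$face_areas[ok], row[ok], sum)
  row_radius[as.integer(names(agg))] <- agg / aw

  region <- rep(NA_character_, n_axial)
  s_mid <- (seq_len(n_axial) - 0.5) * ds
  if (!is.null(regions)) {
    region <- ifelse(s_mid < regions$boundaries[1], "proximal",
                     ifelse(s_mid > regions$boundaries[2], "distal", "stenosis"))
  }
  structure(list(mesh = mesh, ds = ds, dtheta = dtheta,
                 n_axial = n_axial, n_theta = n_theta,
                 face_row = row, face_col = col,
                 s_mid = s_mid, row_radius = row_radius, region = region,
                 theta0 = theta0),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("Bin grid: %d axial rows x %d angular bins (ds %g mm, dtheta %g deg)\n",
              x$n_axial, x$n_theta, x$ds, x$dtheta))
  invisible(x)
}

#' Area-weighted bin averages of a scalar field
#'
#' @param field a [scalar_field()] on the grid's mesh.
#' @param grid a [bin_grid()].
#' @return An object of class `map2d`: matrices `values`, `area` and
#'   `valid` (`n_axial x n_theta`), with the grid's row metadata.
#' @export
bin_average <- function(field, grid) {
  stopifnot(inherits(field, "scalar_field"), inherits(grid, "bin_grid"))
  if (length(field$values) != nrow(grid$mesh$faces))
    stop_config("field and grid refer to different meshes")
  ok <- !is.na(grid$face_row) & field$valid
  idx <- (grid$face_col[ok] - 1L) * grid$n_axial + grid$face_row[ok]
  w <- grid$mesh$face_areas[ok]
  acc_a <- tapply(w, idx, sum)
  acc_v <- tapply(w * field$values[ok], idx, sum)
  ii <- as.integer(names(acc_a))
  area <- matrix(0, grid$n_axial, grid$n_theta)
  vals <- matrix(NA_real_, grid$n_axial, grid$n_theta)
  area[ii] <- acc_a
  vals[ii] <- acc_v / acc_a
  valid <- area > 0
  structure(list(values = vals, area = area, valid = valid,
                 ds = grid$ds, dtheta = grid$dtheta,
                 s_mid = grid$s_mid, region = grid$region,
                 row_radius = grid$row_radius, units = field$units),
            class = "map2d")
}

#' @export
print.map2d <- function(x, ...) {
  cat(sprintf("2D map [%s]: %d x %d bins, %d valid, value range %.4g-%.4g\n",
              x$units, nrow(x$values), ncol(x$values), sum(x$valid),
              min(x$values[x$valid]), max(x$values[x$valid])))
  invisible(x)
}

#' Clip two 2D maps to identical extents
#'
#' Rows are registered on the axial position of minimum wall radius (the
#' stenosis throat) of each map, then both maps are cropped to the common
#' row range and the bin-wise intersection of their validity masks, so the
#' outputs have identical shape and validity.
#'
#' @param mapA,mapB [bin_average()] results with equal `ds` and `dtheta`.
#' @return List with clipped `mapA` and `mapB`.
#' @export
clip_align <- function(mapA, mapB) {
  stopifnot(inherits(mapA, "map2d"), inherits(mapB, "map2d"))
  if (abs(mapA$ds - mapB$ds) > 1e-12 || abs(mapA$dtheta - mapB$dtheta) > 1e-12)
    stop_config("maps have different bin sizes")
  throat_row <- function(m) {
    cand <- which(m$region == "stenosis")
    if (!length(cand)) cand <- seq_along(m$row_radius)
    cand[which.min(m$row_radius[cand])]
  }
  thA <- throat_row(mapA)
  thB <- throat_row(mapB)
  nA <- nrow(mapA$values); nB <- nrow(mapB$values)
  before <- min(thA - 1L, thB - 1L)
  after <- min(nA - thA, nB - thB)
  if (before + after + 1L < 1L) stop_config("maps share no overlapping rows")
  rowsA <- (thA - before):(thA + after)
  rowsB <- (thB - before):(thB + after)
  crop <- function(m, rows) {
    m$values <- m$values[rows, , drop = FALSE]
    m$area <- m$area[rows, , drop = FALSE]
    m$valid <- m$valid[rows, , drop = FALSE]
    m$s_mid <- m$s_mid[rows]
    m$region <- m$region[rows]
    m$row_radius <- m$row_radius[rows]
    m
  }
  A <- crop(mapA, rowsA)
  B <- crop(mapB, rowsB)
  # registered rows describe the same physical stations: label both with
  # the first map's row metadata (regions are defined on the phantom)
  B$s_mid <- A$s_mid
  B$region <- A$region
  both <- A$valid & B$valid
  A$valid <- both; B$valid <- both
  A$values[!both] <- NA_real_
  B$values[!both] <- NA_real_
  list(mapA = A, mapB = B)
}

#' Circumferential or axial means of a 2D map, per region
#'
#' Circumferential: one area-weighted mean per axial row (over the angular
#' bins). Axial: one area-weighted mean per angular bin within each region
#' (over that region's rows). Invalid bins carry no weight; a region or row
#' without any valid bin yields `NA`.
#'
#' @param map a [bin_average()] result whose rows carry region labels.
#' @param direction `"circumferential"` or `"axial"`.
#' @return A data frame: for circumferential, columns `row`, `s_mid`,
#'   `region`, `mean`, `area`; for axial, columns `region`, `bin`,
#'   `theta_mid`, `mean`, `area`.
#' @export
directional_means <- function(map, direction = c("circumferential", "axial")) {
  stopifnot(inherits(map, "map2d"))
  direction <- match.arg(direction)
  if (all(is.na(map$region)))
    stop_config("map rows carry no region labels")
  w <- map$area * map$valid
  if (direction == "circumferential") {
    tot <- rowSums(w)
    vals <- rowSums(ifelse(map$valid, map$values, 0) * w) / ifelse(tot > 0, tot, NA)
    data.frame(row = seq_len(nrow(map$values)), s_mid = map$s_mid,
               region = map$region, mean = vals, area = tot)
  } else {
    out <- list()
    theta_mid <- (seq_len(ncol(map$values)) - 0.5) * map$dtheta
    for (reg in c("proximal", "stenosis", "distal")) {
      rows <- which(map$region == reg)
      if (length(rows) == 0L) next
      wr <- w[rows, , drop = FALSE]
      vr <- ifelse(map$valid[rows, , drop = FALSE],
                   map$values[rows, , drop = FALSE], 0)
      tot <- colSums(wr)
      vals <- colSums(vr * wr) / ifelse(tot > 0, tot, NA)
      out[[reg]] <- data.frame(region = reg,
                               bin = seq_along(vals), theta_mid = theta_mid,
                               mean = vals, area = tot)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  }
}

#' Binary low-value mask of a 2D map
#'
#' Bin-level analogue of [low_wss_mask()]: marks valid bins whose mean is
#' strictly below the threshold. Used to compare low-WSS regions across
#' two different geometries after [clip_align()].
#'
#' @param map a [bin_average()] result.
#' @param threshold cut-off in the map's units (0.5 Pa for WSS).
#' @return Logical matrix of the map's shape with attribute `area`.
#' @export
map_low_mask <- function(map, threshold = 0.5) {
  stopifnot(inherits(map, "map2d"))
  m <- map$valid & !is.na(map$values) & (map$values < threshold)
  attr(m, "area") <- map$area
  m
}

#' Dice similarity of two binary bin masks
#'
#' Area-weighted Dice overlap on a common (clip-aligned) bin grid; each
#' bin's weight is the mean of its areas in the two maps. Both-empty masks
#' give SI = 1 with attribute `both_empty`.
#'
#' @param maskA,maskB results of [map_low_mask()] with identical shapes.
#' @return Dice coefficient in `[0, 1]`.
#' @export
similarity_index_map <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB)))
    stop_config("masks live on incompatible grids")
  wA <- attr(maskA, "area"); wB <- attr(maskB, "area")
  aA <- sum(wA[maskA]); aB <- sum(wB[maskB])
  if (aA + aB == 0) return(structure(1, both_empty = TRUE))
  inter <- (wA + wB) / 2
  2 * sum(inter[maskA & maskB]) / (aA + aB)
}

#' Export a 2D map as CSV with a JSON sidecar, or render it as PNG
#'
#' The CSV is the value matrix (rows = axial bins from the inlet, columns =
#' angular bins from the ostium direction) with `NaN` marking invalid bins;
#' the sidecar records bin sizes, region boundaries and the circumferential
#' origin convention.
#'
#' @param map a [bin_average()] result.
#' @param path output CSV path (sidecar gets `.json` appended to the stem).
#' @return The CSV path, invisibly.
#' @export
write_map2d_csv <- function(map, path) {
  stopifnot(inherits(map, "map2d"))
  vals <- map$values
  vals[!map$valid] <- NaN
  lines <- apply(vals, 1, function(r) paste(fmt_num(r), collapse = ","))
  writeLines(c(paste(sprintf("theta%02d", seq_len(ncol(vals))), collapse = ","),
               lines), path)
  sidecar <- sub("\\.csv$", ".json", path)
  regs <- map$region
  bounds <- if (all(is.na(regs))) NULL else {
    list(proximal_end_mm = map$s_mid[max(which(regs == "proximal"))] + map$ds / 2,
         stenosis_end_mm = map$s_mid[max(which(regs == "stenosis"))] + map$ds / 2)
  }
  write_json_fixed(list(ds_mm = map$ds, dtheta_deg = map$dtheta,
                        n_axial = nrow(vals), n_theta = ncol(vals),
                        units = map$units,
                        region_boundaries = bounds,
                        theta_origin = "direction from centerline to side-branch ostium"),
                   sidecar)
  invisible(path)
}

#' @rdname write_map2d_csv
#' @param cap color-scale saturation cap (same units as the map); values
#'   above it render at the top color, mirroring saturated low-WSS plots.
#'   Default 2 Pa.
#' @export
write_map2d_png <- function(map, path, cap = 2) {
  stopifnot(inherits(map, "map2d"))
  vals <- pmin(map$values, cap)
  vals[!map$valid] <- NA
  grDevices::png(path, width = 640, height = 960)
  op <- graphics::par(mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::image(x = (seq_len(ncol(vals)) - 0.5) * map$dtheta,
                  y = map$s_mid, z = t(vals),
                  col = grDevices::hcl.colors(64, "viridis"),
                  zlim = c(0, cap),
                  xlab = "circumference [deg]", ylab = "axial position [mm]",
                  main = sprintf("2D map [%s], cap %g", map$units, cap))
  invisible(path)
}
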