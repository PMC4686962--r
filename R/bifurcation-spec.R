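#' Parametric specification of a single-ROI coronary bifurcation phantom
#'
#' Describes a main branch with three regions -- a constant-diameter proximal
#' segment, a concentric stenosis, and a constant-diameter distal segment --
#' plus one side branch. This is the ground-truth geometry of a milled
#' phantom region of interest: one stenosis, one side branch, planar layout.
#'
#' All lengths are in millimetres, angles in degrees. The default values
#' describe a mildly diseased bifurcation with a 60% area stenosis located
#' proximal to the side branch; the 1.25 mm proximal radius is a
#' representative coronary radius (the same nominal radius the analytic
#' error model uses), not a measured phantom dimension.
#'
#' @param a_prox proximal lumen radius (mm).
#' @param a_dist distal lumen radius (mm). The default `NULL` sets the
#'   Murray-consistent step-down `(a_prox^3 - side_radius^3)^(1/3)`, which
#'   keeps the wall shear stress homeostatic across the bifurcation under
#'   the cube-law outflow split.
#' @param area_stenosis percent area reduction at the throat, in `[0, 100)`.
#'   The throat radius is `a_prox * sqrt(1 - area_stenosis/100)`.
#' @param stenosis_center arclength of the throat along the main branch (mm).
#' @param stenosis_length full length of the narrowed segment (mm).
#' @param length total main-branch length (mm).
#' @param side_radius side-branch lumen radius (mm).
#' @param side_angle angle between the side branch and the main branch
#'   tangent, in degrees, strictly inside `(0, 180)`.
#' @param ostium_s arclength position of the side-branch ostium on the main
#'   branch (mm); must lie strictly inside the main branch.
#' @param side_length side-branch length measured from the main centerline (mm).
#'
#' @return An object of class `bifurcation_spec`.
#' @examples
#' spec <- bifurcation_spec()
#' spec$main$area_stenosis
#' @export
bifurcation_spec <- function(a_prox = 1.25,
                             a_dist = NULL,
                             area_stenosis = 60,
                             stenosis_center = 9,
                             stenosis_length = 7.5,
                             length = 25,
                             side_radius = 0.85,
                             side_angle = 60,
                             ostium_s = 16,
                             side_length = 8) {
  check_number(a_prox, "a_prox", lower = 0, strict_lower = TRUE)
  check_number(side_radius, "side_radius_pre", lower = 0, strict_lower = TRUE)
  if (is.null(a_dist)) {
    if (side_radius >= a_prox)
      stop_config("Murray-consistent a_dist needs side_radius < a_prox")
    a_dist <- (a_prox^3 - side_radius^3)^(1 / 3)
  }
  check_number(a_dist, "a_dist", lower = 0, strict_lower = TRUE)
  check_number(area_stenosis, "area_stenosis", lower = 0, upper = 100,
               strict_upper = TRUE)
  check_number(stenosis_length, "stenosis_length", lower = 0,
               strict_lower = TRUE)
  check_number(length, "length", lower = 0, strict_lower = TRUE)
  check_number(side_radius, "side_radius", lower = 0, strict_lower = TRUE)
  check_number(side_angle, "side_angle", lower = 0, upper = 180,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(side_length, "side_length", lower = 0, strict_lower = TRUE)
  if (ostium_s <= 0 || ostium_s >= length)
    stop_config("ostium position %g mm must lie strictly inside the main branch (0, %g)",
                ostium_s, length)
  s0 <- stenosis_center - stenosis_length / 2
  s1 <- stenosis_center + stenosis_length / 2
  if (s0 <= 0 || s1 >= length)
    stop_config("stenosis segment [%g, %g] mm must fit strictly inside the main branch (0, %g)",
                s0, s1, length)
  a_throat <- a_prox * sqrt(1 - area_stenosis / 100)
  if (area_stenosis > 0 && a_dist <= a_throat)
    stop_config("distal radius %g mm must exceed the throat radius %g mm, or the minimum lumen would not lie in the stenosis",
                a_dist, a_throat)
  stenosis_position <- if (stenosis_center < ostium_s) "proximal-to-branch" else "distal-to-branch"
  structure(list(
    main = list(a_prox = a_prox, a_dist = a_dist,
                area_stenosis = area_stenosis,
                stenosis_center = stenosis_center,
                stenosis_length = stenosis_length,
                length = length),
    side = list(radius = side_radius, angle = side_angle,
                ostium_s = ostium_s, length = side_length),
    stenosis_position = stenosis_position
  ), class = "bifurcation_spec")
}

#' @export
print.bifurcation_spec <- function(x, ...) {
  cat("Bifurcation phantom spec (single ROI)\n")
  cat(sprintf("  main branch : length %g mm, a_prox %g mm, a_dist %g mm\n",
              x$main$length, x$main$a_prox, x$main$a_dist))
  cat(sprintf("  stenosis    : %g%% area, center %g mm, length %g mm (%s)\n",
              x$main$area_stenosis, x$main$stenosis_center,
              x$main$stenosis_length, x$stenosis_position))
  cat(sprintf("  side branch : radius %g mm, angle %g deg, ostium at %g mm\n",
              x$side$radius, x$side$angle, x$side$ostium_s))
  invisible(x)
}

#' Read or write a phantom spec as a YAML configuration
#'
#' The YAML file carries a `phantom:` block whose keys mirror the
#' [bifurcation_spec()] arguments; missing keys fall back to the defaults,
#' so an empty block reproduces the default phantom.
#'
#' @param path file path.
#' @return `read_bifurcation_spec()` returns a `bifurcation_spec`;
#'   `write_bifurcation_spec()` returns `path` invisibly.
#' @export
read_bifurcation_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  blk <- cfg$phantom %||% cfg
  do.call(bifurcation_spec, blk[names(blk) %in% names(formals(bifurcation_spec))])
}

#' @rdname read_bifurcation_spec
#' @param spec a `bifurcation_spec`.
#' @export
write_bifurcation_spec <- function(spec, path) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  blk <- list(phantom = list(
    a_prox = spec$main$a_prox, a_dist = spec$main$a_dist,
    area_stenosis = spec$main$area_stenosis,
    stenosis_center = spec$main$stenosis_center,
    stenosis_length = spec$main$stenosis_length,
    length = spec$main$length,
    side_radius = spec$side$radius, side_angle = spec$side$angle,
    ostium_s = spec$side$ostium_s, side_length = spec$side$length))
  yaml::write_yaml(blk, path, precision = 15)
  invisible(path)
}
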