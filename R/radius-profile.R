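#' Build the arclength-parameterized lumen radius of the main branch
#'
#' The profile is the geometric ground truth of the phantom main branch:
#' constant proximal radius, a C1 cosine-shaped concentric narrowing whose
#' throat realizes the configured area stenosis, and a constant distal
#' radius. The throat radius follows from the area-stenosis definition
#' `AS = 100 * (1 - (a_throat / a_prox)^2)`.
#'
#' @param spec a [bifurcation_spec()].
#' @param ds sampling interval along the branch (mm).
#' @return An object of class `radius_profile` with fields `s` (mm,
#'   strictly increasing), `a` (mm), and `segment` (factor with levels
#'   proximal/stenosis/distal).
#' @examples
#' prof <- build_radius_profile(bifurcation_spec(), ds = 0.05)
#' min(prof$a) # throat radius, 1.25 * sqrt(0.4)
#' @export
build_radius_profile <- function(spec, ds = 0.05) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  check_number(ds, "ds", lower = 0, strict_lower = TRUE)
  m <- spec$main
  s <- seq(0, m$length, by = ds)
  if (s[length(s)] < m$length) s <- c(s, m$length)
  s0 <- m$stenosis_center - m$stenosis_length / 2
  s1 <- m$stenosis_center + m$stenosis_length / 2
  a_throat <- m$a_prox * sqrt(1 - m$area_stenosis / 100)
  a <- numeric(length(s))
  seg <- character(length(s))
  pre <- s < s0
  post <- s > s1
  mid <- !pre & !post
  a[pre] <- m$a_prox
  a[post] <- m$a_dist
  # two half-cosine arcs pinned at the throat: C1 joins to both constant
  # segments and an exact minimum a_throat at the stenosis center
  u <- (s[mid] - m$stenosis_center) / (m$stenosis_length / 2)  # in [-1, 1]
  h <- function(x) 0.5 * (1 - cos(pi * x))                     # 0 -> 1, C1
  a[mid] <- ifelse(u <= 0,
                   m$a_prox + (a_throat - m$a_prox) * h(u + 1),
                   a_throat + (m$a_dist - a_throat) * h(u))
  seg[pre] <- "proximal"
  seg[mid] <- "stenosis"
  seg[post] <- "distal"
  if (any(a <= 0))
    stop_config("configuration yields non-positive lumen radius")
  radius_profile(s, a, seg)
}

#' Construct a radius profile from raw samples
#'
#' @param s arclength samples (mm), strictly increasing.
#' @param a lumen radius at each sample (mm), strictly positive.
#' @param segment per-sample region tag (`proximal`, `stenosis`, `distal`);
#'   defaults to all-`proximal` for unlabeled measured profiles.
#' @return A `radius_profile`.
#' @export
radius_profile <- function(s, a, segment = NULL) {
  if (length(s) != length(a) || length(s) < 2L)
    stop_config("'s' and 'a' must be equal-length vectors with >= 2 samples")
  if (any(diff(s) <= 0)) stop_config("arclength 's' must be strictly increasing")
  if (any(!is.finite(a)) || any(a <= 0))
    stop_config("lumen radius must be finite and positive everywhere")
  segment <- segment %||% rep("proximal", length(s))
  segment <- factor(segment, levels = c("proximal", "stenosis", "distal"))
  if (anyNA(segment)) stop_config("segment labels must be proximal/stenosis/distal")
  structure(list(s = as.numeric(s), a = as.numeric(a), segment = segment),
            class = "radius_profile")
}

#' @export
print.radius_profile <- function(x, ...) {
  cat(sprintf("Radius profile: %d samples over %g mm, radius %g-%g mm\n",
              length(x$s), max(x$s) - min(x$s), min(x$a), max(x$a)))
  invisible(x)
}

#' Percent area stenosis of a radius profile
#'
#' Computes `100 * (1 - (a_min / a_prox)^2)` where `a_min` is the minimum
#' radius over the stenosis segment and `a_prox` the mean radius of the
#' proximal segment -- the cross-sectional-area reduction at the throat.
#'
#' @param profile a [radius_profile()] with a non-empty stenosis segment.
#' @return Percent area stenosis in `[0, 100)`.
#' @examples
#' area_stenosis_percent(build_radius_profile(bifurcation_spec())) # 60
#' @export
area_stenosis_percent <- function(profile) {
  stopifnot(inherits(profile, "radius_profile"))
  in_sten <- profile$segment == "stenosis"
  in_prox <- profile$segment == "proximal"
  if (!any(in_prox)) stop_config("profile has no proximal segment")
  if (!any(in_sten)) stop_config("profile has an empty stenosis segment")
  a_ref <- mean(profile$a[in_prox])
  a_min <- min(profile$a[in_sten])
  100 * (1 - (a_min / a_ref)^2)
}

#' Detect the three vessel regions from a radius profile
#'
#' The proximal and distal regions are the maximal constant-radius runs at
#' the two ends of the branch (|da/ds| below `slope_tol`); everything in
#' between is labeled stenosis. A fully constant profile yields an empty
#' stenosis region and is flagged with a warning.
#'
#' @param profile a [radius_profile()].
#' @param slope_tol slope tolerance (mm/mm) below which the radius counts as
#'   constant. The default suits generated profiles; increase it for
#'   measured (noisy) profiles.
#' @return An object of class `region_labels`: per-sample factor `segment`
#'   and the two region `boundaries` (mm).
#' @export
detect_regions <- function(profile, slope_tol = 1e-6) {
  stopifnot(inherits(profile, "radius_profile"))
  check_number(slope_tol, "slope_tol", lower = 0, strict_lower = TRUE)
  n <- length(profile$s)
  slope <- abs(diff(profile$a) / diff(profile$s))
  flat <- slope <= slope_tol      # slope of interval i = [s_i, s_{i+1}]
  if (all(flat)) {
    warning("profile is constant: stenosis region is empty")
    seg <- rep("proximal", n)
    half <- profile$s[n]
    return(structure(list(
      segment = factor(seg, levels = c("proximal", "stenosis", "distal")),
      boundaries = c(half, half), empty_stenosis = TRUE),
      class = "region_labels"))
  }
  if (!flat[1L] || !flat[length(flat)])
    stop_config("profile has no constant-radius end segments at slope_tol = %g",
                slope_tol)
  i_first <- which(!flat)[1L]            # first non-flat interval
  i_last <- which(!flat)[sum(!flat)]     # last non-flat interval
  b0 <- profile$s[i_first]
  b1 <- profile$s[i_last + 1L]
  seg <- ifelse(profile$s < b0, "proximal",
                ifelse(profile$s > b1, "distal", "stenosis"))
  structure(list(
    segment = factor(seg, levels = c("proximal", "stenosis", "distal")),
    boundaries = c(b0, b1), empty_stenosis = FALSE),
    class = "region_labels")
}

#' @export
print.region_labels <- function(x, ...) {
  if (isTRUE(x$empty_stenosis)) {
    cat("Region labels: constant profile, empty stenosis region\n")
  } else {
    cat(sprintf("Region labels: proximal < %g mm, stenosis [%g, %g] mm, distal > %g mm\n",
                x$boundaries[1], x$boundaries[1], x$boundaries[2], x$boundaries[2]))
  }
  invisible(x)
}
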