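#' Per-face WSS vector time series
#'
#' Container for the 3D wall shear stress vector on every mesh face at each
#' time sample of one cycle. A single sample (`n_steps = 1`) encodes a
#' steady solution. `valid` marks faces carrying a physical value (faces on
#' the side-branch ostium rim are excluded from analysis).
#'
#' @param mesh a [surface_mesh()].
#' @param wss numeric array `n_faces x 3 x n_steps` (Pa).
#' @param flow the [flow_series()] that produced the samples.
#' @param valid logical per-face validity mask.
#' @return An object of class `wss_series`.
#' @export
wss_series <- function(mesh, wss, flow, valid = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (length(dim(wss)) != 3L || dim(wss)[1] != nrow(mesh$faces) || dim(wss)[2] != 3L)
    stop_config("wss must be an n_faces x 3 x n_steps array")
  if (any(!is.finite(wss))) stop_config("WSS values must be finite")
  valid <- valid %||% rep(TRUE, nrow(mesh$faces))
  structure(list(mesh = mesh, wss = wss, t = flow$t, T = flow$T,
                 n_steps = dim(wss)[3], dt = flow$T / dim(wss)[3],
                 valid = valid),
            class = "wss_series")
}

#' @export
print.wss_series <- function(x, ...) {
  mags <- sqrt(x$wss[, 1, ]^2 + x$wss[, 2, ]^2 + x$wss[, 3, ]^2)
  cat(sprintf("WSS series: %d faces x %d step(s), |tau| %.3g-%.3g Pa\n",
              dim(x$wss)[1], x$n_steps, min(mags), max(mags)))
  invisible(x)
}

#' Synthesize a WSS vector field on a phantom surface
#'
#' Analytic quasi-steady surrogate for the flow solver. Per face and time
#' step: (i) the local WSS magnitude follows the developed-flow expression
#' `tau = q_local (beta + 2) mu_eff / (pi a^3)` with the branch flow split
#' at the ostium by [split_outflow()] and the effective viscosity obtained
#' by evaluating [carreau_viscosity()] at the local wall shear rate
#' `q_local (beta + 2) / (pi a^3)` (which is independent of viscosity, so a
#' single pass is exact); (ii) the direction is the local centerline
#' tangent (antegrade); (iii) inside a crescent starting at the stenosis
#' exit -- angular extent `recirc_angular_extent` centered on the wall
#' opposite the side branch -- the direction is reversed and the magnitude
#' is multiplied by `recirc_magnitude_factor`, tapering linearly to zero at
#' the time-dependent reattachment line
#' `L_r(t) = recirc_length_coeff * Re_jet(t) * (a_dist - a_throat)`
#' (laminar sudden-expansion scaling with the step height); (iv) faces on
#' the ostium rim are flagged invalid.
#'
#' @param geometry list with `mesh` and `centerline` from
#'   [generate_bifurcation_mesh()] / [generate_tube_mesh()] or
#'   [perturb_reconstruction()].
#' @param profile main-branch [radius_profile()] (ground truth or measured).
#' @param flow a [flow_series()].
#' @param params a [surrogate_flow_params()].
#' @param visc a [viscosity_model()].
#' @param regions optional [detect_regions()] result; when absent, regions
#'   are detected from `profile` (used to locate the stenosis exit).
#' @return A [wss_series()].
#' @export
synthesize_wss_field <- function(geometry, profile, flow,
                                 params = surrogate_flow_params(),
                                 visc = viscosity_model(),
                                 regions = NULL) {
  mesh <- geometry$mesh
  cl <- geometry$centerline
  stopifnot(inherits(mesh, "surface_mesh"), inherits(profile, "radius_profile"),
            inherits(flow, "flow_series"), inherits(params, "surrogate_flow_params"),
            inherits(visc, "viscosity_model"))
  if (is.null(cl) || is.null(cl$tangent))
    stop_config("geometry lacks centerline frames")
  meta <- mesh$meta
  face_group <- meta$face_group %||% rep("main", nrow(mesh$faces))
  rim_face <- meta$ostium_rim_face %||% rep(FALSE, nrow(mesh$faces))
  cent <- face_centroids(mesh)
  nf <- nrow(mesh$faces)
  is_side <- face_group == "side"
  is_main <- !is_side

  # local radius and axial coordinate per face
  s_face <- cent[, 3]
  a_face <- numeric(nf)
  a_face[is_main] <- stats::approx(profile$s, profile$a, xout = s_face[is_main],
                                   rule = 2)$y
  spec <- meta$spec
  has_branch <- !is.null(spec)
  if (has_branch) {
    a_side <- spec$side$radius
    a_face[is_side] <- a_side
    frac <- split_outflow(2 * spec$main$a_dist, 2 * a_side)
    s_ostium <- spec$side$ostium_s
  } else {
    frac <- c(main = 1, side = 0)
    s_ostium <- Inf
  }

  # flow fraction seen by each face
  f_face <- rep(1, nf)
  f_face[is_main & s_face >= s_ostium] <- frac[["main"]]
  f_face[is_side] <- frac[["side"]]

  # recirculation crescent support (main branch, distal of the stenosis)
  regions <- regions %||% tryCatch(
    suppressWarnings(detect_regions(profile, slope_tol = 1e-4)),
    error = function(e) NULL)
  has_sten <- !is.null(regions) && !isTRUE(regions$empty_stenosis)
  theta_face <- atan2(cent[, 2], cent[, 1])
  if (has_sten) {
    s_exit <- regions$boundaries[2]
    a_throat_mm <- min(profile$a)
    # expansion step height: distal lumen radius minus throat radius; the
    # reattachment length scales with it (laminar sudden expansion), so the
    # recirculation zone responds to throat reconstruction errors
    a_distal_mm <- mean(profile$a[profile$s > regions$boundaries[2]])
    step_mm <- max(a_distal_mm - a_throat_mm, 0)
    has_sten <- step_mm > 0
    ext <- params$recirc_angular_extent * pi / 180
    in_wedge <- is_main & abs(wrap_angle(theta_face - pi)) <= ext / 2
  }

  q_si <- flow$q * 1e-6                  # ml/s -> m^3/s
  a_m <- a_face * 1e-3                   # mm -> m
  geom_fac <- (params$beta + 2) / (pi * a_m^3)   # shear rate per unit flow
  tangent <- matrix(rep(c(0, 0, 1), each = nf), nf, 3)
  if (has_branch) {
    d_axis <- meta$branch_axis
    tangent[is_side, ] <- matrix(d_axis, sum(is_side), 3, byrow = TRUE)
  }

  wss <- array(0, dim = c(nf, 3, flow$n_steps))
  for (k in seq_len(flow$n_steps)) {
    gamma <- q_si[k] * f_face * geom_fac            # wall shear rate, 1/s
    mu_eff <- carreau_viscosity(gamma, visc)
    tau <- gamma * mu_eff                           # Pa
    sign_ax <- rep(1, nf)
    mag <- tau
    if (has_sten) {
      a_th_m <- a_throat_mm * 1e-3
      v_jet <- q_si[k] / (pi * a_th_m^2)
      re_jet <- visc$rho * v_jet * 2 * a_th_m / carreau_viscosity(
        q_si[k] * (params$beta + 2) / (pi * a_th_m^3), visc)
      L_r <- params$recirc_length_coeff * re_jet * step_mm       # mm
      in_cres <- in_wedge & s_face > s_exit & s_face < s_exit + L_r
      if (any(in_cres)) {
        taper <- 1 - (s_face[in_cres] - s_exit) / L_r
        mag[in_cres] <- tau[in_cres] * params$recirc_magnitude_factor * taper
        sign_ax[in_cres] <- -1
      }
    }
    wss[, , k] <- tangent * (mag * sign_ax)
  }
  wss_series(mesh, wss, flow, valid = !rim_face)
}

#' Export / import a WSS series as per-step CSV tables with a JSON sidecar
#'
#' One CSV per time step with columns `face_id, taux, tauy, tauz` (Pa),
#' plus `<stem>.json` carrying `T`, `n_steps` and units. The same layout is
#' accepted for externally computed (e.g. CFD-exported) fields, given the
#' mesh the faces refer to.
#'
#' @param series a [wss_series()].
#' @param stem output path stem; files are `<stem>_step%03d.csv`.
#' @return `export_wss_series()` the sidecar path; `import_wss_series()` a
#'   [wss_series()].
#' @export
export_wss_series <- function(series, stem) {
  stopifnot(inherits(series, "wss_series"))
  for (k in seq_len(series$n_steps)) {
    df <- data.frame(face_id = seq_len(dim(series$wss)[1]),
                     taux = series$wss[, 1, k],
                     tauy = series$wss[, 2, k],
                     tauz = series$wss[, 3, k])
    write_table_fixed(df, sprintf("%s_step%03d.csv", stem, k))
  }
  sidecar <- paste0(stem, ".json")
  write_json_fixed(list(T = series$T, n_steps = series$n_steps,
                        units = list(stress = "Pa", time = "s")), sidecar)
  sidecar
}

#' @rdname export_wss_series
#' @param mesh the [surface_mesh()] the face ids refer to.
#' @export
import_wss_series <- function(stem, mesh) {
  sidecar <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n_steps <- sidecar$n_steps
  nf <- nrow(mesh$faces)
  wss <- array(0, dim = c(nf, 3, n_steps))
  for (k in seq_len(n_steps)) {
    df <- utils::read.csv(sprintf("%s_step%03d.csv", stem, k))
    if (nrow(df) != nf) stop_config("WSS table step %d does not match the mesh", k)
    wss[df$face_id, , k] <- as.matrix(df[, c("taux", "tauy", "tauz")])
  }
  fl <- flow_series(T = sidecar$T,
                    t = sidecar$T * (seq_len(n_steps) - 1L) / n_steps,
                    q = rep(1, n_steps))
  wss_series(mesh, wss, fl)
}
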