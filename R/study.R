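#' Configuration of a full phantom-vs-reconstruction study
#'
#' Bundles every setting of the experiment: the phantom geometry, the
#' simulated readers (one [perturbation_params()] each), the pulsatile flow
#' (0.8 s cycle in 100 steps, inlet peak velocity 0.15 m/s), the Carreau
#' viscosity model, the surrogate flow parameters, the low-WSS threshold
#' (0.5 Pa), the equivalence margins (0.25 Pa for WSS/TAWSS, 0.05 for OSI),
#' and the 2D binning (0.45 mm x 22.5 deg). The configuration round-trips
#' losslessly through YAML via [write_study_config()].
#'
#' @param spec a [bifurcation_spec()].
#' @param readers list of [perturbation_params()], one per simulated
#'   reader; default two readers with seeds 1 and 2.
#' @param T cycle period (s).
#' @param n_steps time steps per cycle.
#' @param v_peak inlet peak velocity (m/s).
#' @param visc a [viscosity_model()].
#' @param surrogate a [surrogate_flow_params()].
#' @param low_wss_threshold low-WSS cut-off (Pa).
#' @param margin_wss equivalence margin for WSS and TAWSS (Pa).
#' @param margin_osi equivalence margin for OSI (dimensionless).
#' @param alpha TOST significance level.
#' @param ds,dtheta 2D bin sizes (mm, deg).
#' @param resolution mesh edge length (mm).
#' @return An object of class `study_config`.
#' @export
study_config <- function(spec = bifurcation_spec(),
                         readers = list(
                           perturbation_params(radial_sd = 0.08, seed = 1L,
                                               branch_angle_offset = 2),
                           perturbation_params(radial_sd = 0.08, seed = 2L,
                                               branch_angle_offset = -2)),
                         T = 0.8, n_steps = 100, v_peak = 0.15,
                         visc = viscosity_model(),
                         surrogate = surrogate_flow_params(v_peak_inlet = v_peak),
                         low_wss_threshold = 0.5,
                         margin_wss = 0.25, margin_osi = 0.05, alpha = 0.05,
                         ds = 0.45, dtheta = 22.5, resolution = 0.25) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  if (!length(readers) || !all(vapply(readers, inherits, TRUE, "perturbation_params")))
    stop_config("readers must be a non-empty list of perturbation_params")
  structure(list(spec = spec, readers = readers,
                 T = T, n_steps = n_steps, v_peak = v_peak,
                 visc = visc, surrogate = surrogate,
                 low_wss_threshold = low_wss_threshold,
                 margin_wss = margin_wss, margin_osi = margin_osi,
                 alpha = alpha, ds = ds, dtheta = dtheta,
                 resolution = resolution),
            class = "study_config")
}

#' Write or read a study configuration as YAML
#' @param config a [study_config()].
#' @param path file path.
#' @return Writers return `path` invisibly; the reader a `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- list(
    phantom = unclass(config$spec),
    readers = lapply(config$readers, unclass),
    flow = list(T = config$T, n_steps = config$n_steps, v_peak = config$v_peak),
    viscosity = unclass(config$visc),
    surrogate = unclass(config$surrogate),
    thresholds = list(low_wss = config$low_wss_threshold,
                      margin_wss = config$margin_wss,
                      margin_osi = config$margin_osi, alpha = config$alpha),
    binning = list(ds = config$ds, dtheta = config$dtheta),
    resolution = config$resolution)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  ph <- x$phantom
  spec <- bifurcation_spec(
    a_prox = ph$main$a_prox, a_dist = ph$main$a_dist,
    area_stenosis = ph$main$area_stenosis,
    stenosis_center = ph$main$stenosis_center,
    stenosis_length = ph$main$stenosis_length, length = ph$main$length,
    side_radius = ph$side$radius, side_angle = ph$side$angle,
    ostium_s = ph$side$ostium_s, side_length = ph$side$length)
  readers <- lapply(x$readers, function(r) do.call(perturbation_params, r))
  study_config(spec = spec, readers = readers,
               T = x$flow$T, n_steps = x$flow$n_steps, v_peak = x$flow$v_peak,
               visc = do.call(viscosity_model, x$viscosity),
               surrogate = do.call(surrogate_flow_params, x$surrogate),
               low_wss_threshold = x$thresholds$low_wss,
               margin_wss = x$thresholds$margin_wss,
               margin_osi = x$thresholds$margin_osi,
               alpha = x$thresholds$alpha,
               ds = x$binning$ds, dtheta = x$binning$dtheta,
               resolution = x$resolution)
}

# metrics chain for one geometry: steady + transient fields, maps, means
analyze_geometry <- function(geometry, profile, regions, config) {
  q_mean <- inlet_flow_from_peak_velocity(config$spec$main$a_prox, config$v_peak)
  steady <- synthesize_wss_field(geometry, profile, steady_flow(q_mean),
                                 config$surrogate, config$visc, regions)
  puls <- synthesize_wss_field(geometry, profile,
                               coronary_waveform(config$T, config$n_steps, q_mean),
                               config$surrogate, config$visc, regions)
  grid <- build_bin_grid(geometry$mesh, geometry$centerline,
                         ds = config$ds, dtheta = config$dtheta,
                         regions = regions)
  f_wss <- wss_magnitude(steady)
  f_tawss <- tawss(puls)
  f_osi <- osi(puls)
  list(steady = steady, grid = grid,
       fields = list(wss = f_wss, tawss = f_tawss, osi = f_osi),
       maps = list(wss = bin_average(f_wss, grid),
                   tawss = bin_average(f_tawss, grid),
                   osi = bin_average(f_osi, grid)),
       low_mask = low_wss_mask(f_wss, config$low_wss_threshold),
       q_mean = q_mean)
}

# per-region mean absolute difference between two clip-aligned maps
region_mad <- function(mapA, mapB) {
  ok <- mapA$valid
  d <- abs(mapA$values - mapB$values)[ok]
  w <- ((mapA$area + mapB$area) / 2)[ok]
  reg <- matrix(mapA$region, nrow(mapA$values), ncol(mapA$values))[ok]
  vapply(c("proximal", "stenosis", "distal"), function(r) {
    in_r <- reg == r & !is.na(reg)
    if (!any(in_r)) return(NA_real_)
    sum(d[in_r] * w[in_r]) / sum(w[in_r])
  }, 1)
}

#' Run the full phantom-vs-reconstruction experiment
#'
#' Generates the phantom, simulates each reader's reconstruction, runs the
#' surrogate flow model on every geometry, computes WSS/TAWSS/OSI, unwraps
#' them onto the 2D grid, and compares each reconstruction against the
#' phantom: low-WSS similarity index, per-region mean absolute differences,
#' and percentage-of-equivalence per region for the three metrics in both
#' averaging directions. All tables are written as fixed-format CSV/JSON
#' (re-running the same configuration reproduces them byte for byte),
#' 2D maps also as PNG, meshes as ASCII PLY, and a manifest records the
#' full configuration and seeds.
#'
#' @param config a [study_config()].
#' @param out_dir output directory, created if missing; `NULL` skips all
#'   file output.
#' @param write_png also render 2D map heat maps (default `TRUE` when
#'   `out_dir` is set).
#' @return Invisibly, a list with `geometry_table`, `si_table`,
#'   `mad_table`, `equivalence_table`, the per-reader detail objects, and
#'   `manifest`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      write_png = !is.null(out_dir)) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_config("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  profile <- stage("generate", build_radius_profile(config$spec,
                                                    ds = config$resolution / 2))
  regions <- stage("generate", detect_regions(profile))
  phantom <- stage("generate", generate_bifurcation_mesh(config$spec,
                                                         config$resolution,
                                                         profile = profile))
  ph <- stage("metrics", analyze_geometry(phantom, profile, regions, config))

  frac <- split_outflow(2 * config$spec$main$a_dist, 2 * config$spec$side$radius)
  geometry_rows <- list(data.frame(
    model = "phantom", dr_prox_mm = 0, dr_sten_mm = 0, dr_dist_mm = 0,
    hausdorff_mm = 0, area_stenosis_pct = area_stenosis_percent(profile),
    inflow_ml_s = ph$q_mean,
    outflow_main_pct = 100 * frac[["main"]],
    outflow_side_pct = 100 * frac[["side"]]))

  si_rows <- list()
  mad_rows <- list()
  eq_rows <- list()
  readers_out <- list()
  for (i in seq_along(config$readers)) {
    rp <- config$readers[[i]]
    nm <- sprintf("reader%d", i)
    rec <- stage("perturb", perturb_reconstruction(phantom, rp))
    mprof <- stage("perturb", measured_radius_profile(rec$mesh, profile))
    rd <- stage("metrics", analyze_geometry(rec, mprof, regions, config))

    dr <- mprof$a - stats::approx(profile$s, profile$a, xout = mprof$s)$y
    seg <- as.character(mprof$segment)
    geometry_rows[[i + 1]] <- data.frame(
      model = nm,
      dr_prox_mm = mean(abs(dr[seg == "proximal"])),
      dr_sten_mm = mean(abs(dr[seg == "stenosis"])),
      dr_dist_mm = mean(abs(dr[seg == "distal"])),
      hausdorff_mm = stage("compare", mean_hausdorff(phantom$mesh, rec$mesh)),
      area_stenosis_pct = area_stenosis_percent(mprof),
      inflow_ml_s = rd$q_mean,
      outflow_main_pct = 100 * frac[["main"]],
      outflow_side_pct = 100 * frac[["side"]])

    aligned <- stage("compare", lapply(
      stats::setNames(nm = c("wss", "tawss", "osi")),
      function(metric) clip_align(ph$maps[[metric]], rd$maps[[metric]])))

    si_steady <- similarity_index_map(
      map_low_mask(aligned$wss$mapA, config$low_wss_threshold),
      map_low_mask(aligned$wss$mapB, config$low_wss_threshold))
    si_tawss <- similarity_index_map(
      map_low_mask(aligned$tawss$mapA, config$low_wss_threshold),
      map_low_mask(aligned$tawss$mapB, config$low_wss_threshold))
    si_rows[[i]] <- data.frame(model = nm, si_steady = as.numeric(si_steady),
                               si_tawss = as.numeric(si_tawss),
                               low_wss_fraction_phantom = ph$low_mask$area_fraction,
                               low_wss_fraction_reader = rd$low_mask$area_fraction)

    for (metric in c("wss", "tawss", "osi")) {
      mads <- region_mad(aligned[[metric]]$mapA, aligned[[metric]]$mapB)
      mad_rows[[length(mad_rows) + 1]] <- data.frame(
        model = nm, metric = metric,
        proximal = mads[["proximal"]], stenosis = mads[["stenosis"]],
        distal = mads[["distal"]])
      margin <- if (metric == "osi") config$margin_osi else config$margin_wss
      for (direction in c("circumferential", "axial")) {
        eq <- stage("compare", equivalence_map(
          directional_means(aligned[[metric]]$mapA, direction),
          directional_means(aligned[[metric]]$mapB, direction),
          margin = margin, alpha = config$alpha))
        eq_rows[[length(eq_rows) + 1]] <- data.frame(
          model = nm, metric = metric, direction = direction,
          margin = margin,
          proximal = eq$percent[["proximal"]],
          stenosis = eq$percent[["stenosis"]],
          distal = eq$percent[["distal"]])
      }
    }
    readers_out[[nm]] <- list(geometry = rec, profile = mprof, analysis = rd,
                              aligned = aligned)
  }

  geometry_table <- do.call(rbind, geometry_rows)
  si_table <- do.call(rbind, si_rows)
  mad_table <- do.call(rbind, mad_rows)
  equivalence_table <- do.call(rbind, eq_rows)
  manifest <- list(
    package = "wssphantom",
    version = as.character(utils::packageVersion("wssphantom")),
    seeds = vapply(config$readers, `[[`, 1L, "seed"),
    n_readers = length(config$readers),
    config_yaml = "config.yaml")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stage("report", {
      write_study_config(config, file.path(out_dir, "config.yaml"))
      write_mesh_ply(phantom$mesh, file.path(out_dir, "phantom.ply"))
      write_table_fixed(geometry_table, file.path(out_dir, "geometry_table.csv"))
      write_table_fixed(si_table, file.path(out_dir, "si_table.csv"))
      write_table_fixed(mad_table, file.path(out_dir, "mad_table.csv"))
      write_table_fixed(equivalence_table,
                        file.path(out_dir, "equivalence_table.csv"))
      for (metric in c("wss", "tawss", "osi")) {
        write_map2d_csv(ph$maps[[metric]],
                        file.path(out_dir, sprintf("phantom_map_%s.csv", metric)))
        if (write_png)
          write_map2d_png(ph$maps[[metric]],
                          file.path(out_dir, sprintf("phantom_map_%s.png", metric)),
                          cap = if (metric == "osi") 0.5 else 2)
      }
      for (nm in names(readers_out)) {
        write_mesh_ply(readers_out[[nm]]$geometry$mesh,
                       file.path(out_dir, sprintf("%s.ply", nm)))
        for (metric in c("wss", "tawss", "osi"))
          write_map2d_csv(readers_out[[nm]]$analysis$maps[[metric]],
                          file.path(out_dir, sprintf("%s_map_%s.csv", nm, metric)))
      }
      write_json_fixed(manifest, file.path(out_dir, "manifest.json"))
    })
  }
  invisible(list(geometry_table = geometry_table, si_table = si_table,
                 mad_table = mad_table, equivalence_table = equivalence_table,
                 phantom = list(geometry = phantom, profile = profile,
                                regions = regions, analysis = ph),
                 readers = readers_out, manifest = manifest))
}
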