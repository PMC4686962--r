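test_that("without a stenosis the surrogate collapses to the closed form", {
  sp <- bifurcation_spec(area_stenosis = 0, side_radius = 0.6)
  prof <- build_radius_profile(sp, ds = 0.15)
  g <- generate_bifurcation_mesh(sp, 0.3, profile = prof)
  q_ml <- inlet_flow_from_peak_velocity(sp$main$a_prox)
  w <- synthesize_wss_field(g, prof, steady_flow(q_ml))
  f <- wss_magnitude(w)
  cent <- face_centroids(g$mesh)
  frac <- split_outflow(2 * sp$main$a_dist, 2 * sp$side$radius)

  # independent evaluation: shear rate -> Carreau viscosity -> stress
  expected <- function(q_si, a_mm) {
    gam <- q_si * 4 / (pi * (a_mm * 1e-3)^3)
    gam * carreau_viscosity(gam)
  }
  q_si <- q_ml * 1e-6
  grp <- g$mesh$meta$face_group
  ok <- f$valid
  pre <- ok & grp == "main" & cent[, 3] < sp$side$ostium_s - 1
  post <- ok & grp == "main" & cent[, 3] > sp$side$ostium_s + 1
  side <- ok & grp == "side"
  a_of <- function(s) approx(prof$s, prof$a, xout = s)$y
  expect_lt(max(abs(f$values[pre] - expected(q_si, a_of(cent[pre, 3])))) /
              expected(q_si, sp$main$a_prox), 0.02)
  expect_lt(max(abs(f$values[post] -
                      expected(q_si * frac[["main"]], a_of(cent[post, 3])))) /
              expected(q_si * frac[["main"]], sp$main$a_dist), 0.02)
  expect_lt(max(abs(f$values[side] -
                      expected(q_si * frac[["side"]], sp$side$radius))) /
              expected(q_si * frac[["side"]], sp$side$radius), 0.02)
})

test_that("steady default phantom has an order-1-Pa proximal WSS and a crescent", {
  ph <- get_phantom()
  q_ml <- inlet_flow_from_peak_velocity()
  w <- synthesize_wss_field(ph$geometry, ph$profile, steady_flow(q_ml),
                            regions = ph$regions)
  f <- wss_magnitude(w)
  cent <- face_centroids(ph$geometry$mesh)
  prox <- f$valid & ph$geometry$mesh$meta$face_group == "main" &
    cent[, 3] < ph$regions$boundaries[1]
  expect_gt(mean(f$values[prox]), 0.5)
  expect_lt(mean(f$values[prox]), 2)

  # retrograde crescent: negative axial WSS just distal of the stenosis exit
  wz <- w$wss[, 3, 1]
  cres <- which(wz < 0)
  expect_gt(length(cres), 0)
  expect_true(all(cent[cres, 3] > ph$regions$boundaries[2]))
  # reattachment: beyond the most distal retrograde face flow is antegrade
  s_reattach <- max(cent[cres, 3])
  far <- f$valid & cent[, 3] > s_reattach + 0.5 &
    ph$geometry$mesh$meta$face_group == "main"
  expect_true(all(wz[far] > 0))
})

test_that("throat-to-proximal WSS ratio follows the cubic law", {
  ph <- get_phantom()
  q_ml <- inlet_flow_from_peak_velocity()
  # Newtonian fluid isolates the pure geometry scaling
  visc <- viscosity_model(mu0 = 3.5e-3 + 1e-9, mu_inf = 3.5e-3)
  w <- synthesize_wss_field(ph$geometry, ph$profile, steady_flow(q_ml),
                            visc = visc, regions = ph$regions)
  f <- wss_magnitude(w)
  cent <- face_centroids(ph$geometry$mesh)
  main <- ph$geometry$mesh$meta$face_group == "main" & f$valid
  thr <- main & abs(cent[, 3] - default_spec$main$stenosis_center) < 0.2
  prox <- main & cent[, 3] < 2
  ratio <- mean(f$values[thr]) / mean(f$values[prox])
  a_throat <- min(ph$profile$a)
  expect_equal(ratio, (default_spec$main$a_prox / a_throat)^3, tolerance = 0.01)
})

test_that("proximal WSS scales as 1/a^3 under uniform dilation at fixed flow", {
  q_ml <- 0.37
  get_prox <- function(scale) {
    sp <- bifurcation_spec(a_prox = 1.25 * scale, a_dist = 1.1 * scale,
                           side_radius = 0.85 * scale)
    prof <- build_radius_profile(sp, ds = 0.15)
    g <- generate_bifurcation_mesh(sp, 0.3 * scale, profile = prof)
    visc <- viscosity_model(mu0 = 3.5e-3 + 1e-9, mu_inf = 3.5e-3)
    f <- wss_magnitude(synthesize_wss_field(g, prof, steady_flow(q_ml),
                                            visc = visc))
    cent <- face_centroids(g$mesh)
    mean(f$values[f$valid & g$mesh$meta$face_group == "main" & cent[, 3] < 3])
  }
  expect_equal(get_prox(1.3) / get_prox(1), 1 / 1.3^3, tolerance = 0.01)
})

test_that("steady synthesis equals the time-average of a constant waveform", {
  ph <- get_phantom()
  q_ml <- 0.37
  st <- synthesize_wss_field(ph$geometry, ph$profile, steady_flow(q_ml),
                             regions = ph$regions)
  const <- coronary_waveform(q_mean = q_ml, n_steps = 20,
                             systolic_weight = 0, diastolic_weight = 0)
  tr <- synthesize_wss_field(ph$geometry, ph$profile, const,
                             regions = ph$regions)
  expect_equal(tawss(tr)$values, wss_magnitude(st)$values, tolerance = 1e-9)
})

test_that("pulsatile phantom flow produces an OSI band up to ~0.5", {
  ph <- get_phantom()
  fl <- coronary_waveform(q_mean = inlet_flow_from_peak_velocity())
  w <- synthesize_wss_field(ph$geometry, ph$profile, fl, regions = ph$regions)
  o <- osi(w)
  cent <- face_centroids(ph$geometry$mesh)
  expect_gte(min(o$values[o$valid]), 0)
  expect_lte(max(o$values[o$valid]), 0.5)
  expect_gt(max(o$values[o$valid]), 0.3)
  # oscillation is confined distal of the stenosis exit
  osc <- o$valid & o$values > 0.05
  expect_true(all(cent[osc, 3] > ph$regions$boundaries[2] - 0.5))
  # proximal OSI is zero
  prox <- o$valid & cent[, 3] < ph$regions$boundaries[1]
  expect_equal(max(o$values[prox]), 0)
})

test_that("WSS series round-trip through per-step CSV with sidecar", {
  ph <- get_phantom()
  fl <- coronary_waveform(q_mean = 0.37, n_steps = 3)
  w <- synthesize_wss_field(ph$geometry, ph$profile, fl, regions = ph$regions)
  stem <- file.path(withr::local_tempdir(), "field")
  export_wss_series(w, stem)
  w2 <- import_wss_series(stem, ph$geometry$mesh)
  expect_equal(w2$n_steps, 3L)
  expect_equal(w2$wss, w$wss, tolerance = 1e-7)
  expect_equal(w2$T, w$T)
})
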