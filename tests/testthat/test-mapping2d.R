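test_that("bin grid dimensions follow the spacing contract", {
  g <- generate_tube_mesh(9, radius = 1.25, resolution = 0.3)
  grid <- build_bin_grid(g$mesh, g$centerline, ds = 0.45, dtheta = 22.5)
  expect_equal(grid$n_axial, 20L)
  expect_equal(grid$n_theta, 16L)
  expect_error(build_bin_grid(g$mesh, g$centerline, dtheta = 21),
               "does not divide")
  # uniform cylinder at fine resolution: all bins valid, near-equal areas
  # (centroid assignment quantizes areas at the mesh scale, so the mesh
  # must be much finer than the bins)
  gf <- generate_tube_mesh(9, radius = 1.25, resolution = 0.09)
  gridf <- build_bin_grid(gf$mesh, gf$centerline)
  mf <- bin_average(scalar_field(gf$mesh, rep(1, nrow(gf$mesh$faces))), gridf)
  expect_true(all(mf$valid))
  expect_lt(diff(range(mf$area)) / mean(mf$area), 0.05)
})

test_that("bin averages preserve uniform fields, monotonicity and totals", {
  g <- generate_tube_mesh(9, radius = 1.25, resolution = 0.3)
  grid <- build_bin_grid(g$mesh, g$centerline)
  n <- nrow(g$mesh$faces)
  # uniform field
  m <- bin_average(scalar_field(g$mesh, rep(3.3, n)), grid)
  expect_equal(m$values[m$valid], rep(3.3, sum(m$valid)))
  # field equal to the axial coordinate: row means monotone
  z <- face_centroids(g$mesh)[, 3]
  mz <- bin_average(scalar_field(g$mesh, z), grid)
  expect_true(all(diff(rowMeans(mz$values)) > 0))
  # area conservation (cylinder: all faces land in bins except the tail
  # shorter than one row)
  in_rows <- !is.na(grid$face_row)
  expect_equal(sum(m$area), sum(g$mesh$face_areas[in_rows]), tolerance = 1e-9)
  # grand mean invariance
  set.seed(6)
  vals <- runif(n)
  mr <- bin_average(scalar_field(g$mesh, vals), grid)
  lhs <- sum(mr$values[mr$valid] * mr$area[mr$valid]) / sum(mr$area[mr$valid])
  rhs <- sum(vals[in_rows] * g$mesh$face_areas[in_rows]) /
    sum(g$mesh$face_areas[in_rows])
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("rotationally symmetric fields unwrap to constant rows", {
  ph <- get_phantom()
  w <- synthesize_wss_field(ph$geometry, ph$profile, steady_flow(0.37),
                            regions = ph$regions)
  # suppress the crescent to keep rotational symmetry: no-stenosis profile
  flat <- radius_profile(ph$profile$s, rep(1.25, length(ph$profile$s)))
  wsym <- synthesize_wss_field(ph$geometry, flat, steady_flow(0.37))
  grid <- build_bin_grid(ph$geometry$mesh, ph$geometry$centerline,
                         regions = ph$regions)
  m <- bin_average(wss_magnitude(wsym), grid)
  full_rows <- which(rowSums(m$valid) == 16L)
  for (r in full_rows) {
    vals <- m$values[r, ]
    expect_lt(diff(range(vals)) / mean(vals), 0.01)
  }
  # ostium hole: some bins around the branch carry no wall
  expect_lt(sum(m$valid), 16L * nrow(m$valid))
})

test_that("clip_align registers rows on the throat and intersects validity", {
  ph <- get_phantom()
  grid <- build_bin_grid(ph$geometry$mesh, ph$geometry$centerline,
                         regions = ph$regions)
  w <- wss_magnitude(synthesize_wss_field(ph$geometry, ph$profile,
                                          steady_flow(0.37),
                                          regions = ph$regions))
  m <- bin_average(w, grid)
  al <- clip_align(m, m)
  expect_identical(al$mapA$values, m$values)
  expect_identical(al$mapB$valid, al$mapA$valid)

  # same map missing two end rows: both clipped to the shorter extent
  crop <- m
  keep <- 3:nrow(m$values)
  crop$values <- m$values[keep, ]; crop$area <- m$area[keep, ]
  crop$valid <- m$valid[keep, ]; crop$s_mid <- m$s_mid[keep]
  crop$region <- m$region[keep]; crop$row_radius <- m$row_radius[keep]
  al2 <- clip_align(m, crop)
  expect_equal(nrow(al2$mapA$values), length(keep))
  expect_equal(al2$mapA$values[al2$mapA$valid], al2$mapB$values[al2$mapB$valid])
})

test_that("directional means weight by area and respect invalid bins", {
  ph <- get_phantom()
  grid <- build_bin_grid(ph$geometry$mesh, ph$geometry$centerline,
                         regions = ph$regions)
  n <- nrow(ph$geometry$mesh$faces)
  m <- bin_average(scalar_field(ph$geometry$mesh, rep(2, n)), grid)
  cm <- directional_means(m, "circumferential")
  am <- directional_means(m, "axial")
  expect_equal(cm$mean[!is.na(cm$mean)],
               rep(2, sum(!is.na(cm$mean))), tolerance = 1e-12)
  expect_equal(am$mean[!is.na(am$mean)],
               rep(2, sum(!is.na(am$mean))), tolerance = 1e-12)
  expect_setequal(unique(am$region), c("proximal", "stenosis", "distal"))

  # hand-computed weighted mean on a 2-row toy map with one invalid bin
  toy <- m
  toy$values <- matrix(1, 2, 16); toy$values[1, 2] <- 5
  toy$area <- matrix(1, 2, 16); toy$area[1, 2] <- 3
  toy$valid <- matrix(TRUE, 2, 16); toy$valid[1, 5] <- FALSE
  toy$s_mid <- c(0.225, 0.675); toy$region <- c("proximal", "proximal")
  cm2 <- directional_means(toy, "circumferential")
  expect_equal(cm2$mean[1], (14 * 1 + 3 * 5) / 17)  # 15 valid bins, one heavy
  expect_equal(cm2$mean[2], 1)
  am2 <- directional_means(toy, "axial")
  expect_equal(am2$mean[am2$bin == 5], 1)   # invalid bin excluded from row 1
  expect_equal(am2$mean[am2$bin == 2], (5 * 3 + 1) / 4)
})

test_that("2D maps round-trip through CSV and render to PNG", {
  ph <- get_phantom()
  grid <- build_bin_grid(ph$geometry$mesh, ph$geometry$centerline,
                         regions = ph$regions)
  w <- wss_magnitude(synthesize_wss_field(ph$geometry, ph$profile,
                                          steady_flow(0.37),
                                          regions = ph$regions))
  m <- bin_average(w, grid)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "map.csv")
  write_map2d_csv(m, csv)
  got <- as.matrix(utils::read.csv(csv))
  expect_equal(dim(got), dim(m$values))
  expect_equal(unname(got[m$valid]), m$values[m$valid], tolerance = 1e-7)
  expect_true(all(is.nan(got[!m$valid])))
  expect_true(file.exists(file.path(dir, "map.json")))
  png <- file.path(dir, "map.png")
  write_map2d_png(m, png)
  expect_gt(file.info(png)$size, 0)
})
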