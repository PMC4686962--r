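test_that("radius profile realizes the configured area stenosis exactly", {
  prof <- get_phantom()$profile
  expect_equal(area_stenosis_percent(prof), 60, tolerance = 1e-9)
  expect_equal(min(prof$a), 1.25 * sqrt(0.4), tolerance = 1e-9)

  # identity and hand-derived cases
  flat <- build_radius_profile(bifurcation_spec(area_stenosis = 0,
                                                a_dist = 1.25,
                                                side_radius = 0.6))
  expect_equal(diff(range(flat$a[flat$segment != "stenosis"])), 0,
               tolerance = 1e-12)
  p75 <- build_radius_profile(bifurcation_spec(a_prox = 2, a_dist = 2,
                                               area_stenosis = 75,
                                               side_radius = 0.8))
  expect_equal(min(p75$a), 1.0, tolerance = 1e-9)
  expect_equal(area_stenosis_percent(p75), 75, tolerance = 1e-9)
})

test_that("area stenosis round-trips for arbitrary valid specs", {
  set.seed(11)
  for (i in 1:15) {
    as_pct <- runif(1, 15, 90)
    a_prox <- runif(1, 0.9, 2)
    a_throat <- a_prox * sqrt(1 - as_pct / 100)
    sp <- bifurcation_spec(a_prox = a_prox,
                           a_dist = runif(1, min(1.05 * a_throat, 0.99 * a_prox),
                                          a_prox),
                           area_stenosis = as_pct, side_radius = 0.5)
    prof <- build_radius_profile(sp, ds = 0.02)
    expect_equal(area_stenosis_percent(prof), as_pct, tolerance = 1e-6)
    # minimum radius lies inside the stenosis segment
    expect_equal(as.character(prof$segment[which.min(prof$a)]), "stenosis")
  }
})

test_that("region detection recovers the configured stenosis segment", {
  ph <- get_phantom()
  r <- ph$regions
  s0 <- default_spec$main$stenosis_center - default_spec$main$stenosis_length / 2
  s1 <- default_spec$main$stenosis_center + default_spec$main$stenosis_length / 2
  ds <- diff(ph$profile$s[1:2])
  expect_lt(abs(r$boundaries[1] - s0), ds + 1e-9)
  expect_lt(abs(r$boundaries[2] - s1), ds + 1e-9)
  expect_equal(levels(r$segment), c("proximal", "stenosis", "distal"))

  # constant profile: empty stenosis, flagged
  flat <- radius_profile(seq(0, 10, 0.5), rep(1.2, 21))
  expect_warning(rl <- detect_regions(flat), "constant")
  expect_true(rl$empty_stenosis)

  # tapered ends below tolerance: error
  taper <- radius_profile(seq(0, 10, 0.5), seq(1, 2, length.out = 21))
  expect_error(detect_regions(taper, slope_tol = 1e-6), "constant-radius")
})

test_that("spec validation rejects impossible configurations", {
  expect_error(bifurcation_spec(area_stenosis = 100), "area_stenosis")
  expect_error(bifurcation_spec(stenosis_center = 2, stenosis_length = 7.5),
               "fit strictly inside")
  expect_error(bifurcation_spec(ostium_s = 30), "strictly inside")
  expect_error(bifurcation_spec(side_angle = 0), "side_angle")
})

test_that("phantom spec round-trips through YAML", {
  sp <- bifurcation_spec(a_prox = 1.4, area_stenosis = 55, side_angle = 45)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_bifurcation_spec(sp, path)
  sp2 <- read_bifurcation_spec(path)
  expect_equal(sp2$main, sp$main)
  expect_equal(sp2$side, sp$side)
})
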