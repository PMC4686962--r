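test_that("TAWSS averages the magnitude over the cycle", {
  # constant magnitude
  s <- make_series(rep(2.5, 10))
  expect_equal(tawss(s)$values, rep(2.5, nrow(s$mesh$faces)))
  # sign flip half-way: magnitude is direction-blind
  vecs <- rbind(matrix(rep(c(0, 0, 1.5), 50), ncol = 3, byrow = TRUE),
                matrix(rep(c(0, 0, -1.5), 50), ncol = 3, byrow = TRUE))
  expect_equal(tawss(make_vector_series(vecs))$values[1], 1.5)
  # rectified sine: mean of A|sin| = 2A/pi
  A <- 3
  t <- (0:99) / 100
  s3 <- make_series(abs(A * sin(2 * pi * t)) + 1e-15)
  expect_equal(tawss(s3)$values[1], 2 * A / pi, tolerance = 0.001)
  # steady series passes through
  expect_equal(wss_magnitude(make_series(1.2))$values[1], 1.2)
})

test_that("OSI hits its defining values exactly", {
  n <- nrow(get_tiny_tube()$mesh$faces)
  # unidirectional with arbitrary positive magnitudes
  set.seed(4)
  s1 <- make_series(runif(100, 0.1, 3))
  expect_equal(osi(s1)$values, rep(0, n))
  # balanced alternation: 0.5
  vecs <- rbind(matrix(rep(c(1, 0, 0), 50), ncol = 3, byrow = TRUE),
                matrix(rep(c(-1, 0, 0), 50), ncol = 3, byrow = TRUE))
  expect_equal(osi(make_vector_series(vecs))$values, rep(0.5, n))
  # uniformly rotating vector: integral vanishes, OSI 0.5
  th <- 2 * pi * (0:99) / 100
  rot <- cbind(cos(th), sin(th), 0)
  expect_equal(osi(make_vector_series(rot))$values, rep(0.5, n),
               tolerance = 1e-12)
  # all-zero series: no oscillation, OSI 0 by convention
  expect_equal(osi(make_series(rep(0, 10)))$values, rep(0, n))
  # range invariant on random series
  set.seed(9)
  for (i in 1:5) {
    vs <- matrix(rnorm(60), ncol = 3)
    o <- osi(make_vector_series(vs))$values
    expect_true(all(o >= 0 & o <= 0.5))
  }
  expect_error(osi(make_series(1)), "at least 2")
})

test_that("TAWSS dominates the vector average (triangle inequality)", {
  set.seed(5)
  for (i in 1:5) {
    vs <- matrix(rnorm(30), ncol = 3)
    s <- make_vector_series(vs)
    ta <- tawss(s)$values[1]
    avg <- sqrt(sum(colMeans(vs)^2))
    expect_gte(ta + 1e-12, avg)
    expect_lte(ta, max(sqrt(rowSums(vs^2))) + 1e-12)
  }
})

test_that("low-WSS mask is strict and area-weighted", {
  g <- get_tiny_tube()
  n <- nrow(g$mesh$faces)
  f_hi <- scalar_field(g$mesh, rep(1, n))
  f_lo <- scalar_field(g$mesh, rep(0.2, n))
  expect_equal(low_wss_mask(f_hi, 0.5)$area_fraction, 0)
  expect_equal(low_wss_mask(f_lo, 0.5)$area_fraction, 1)
  # boundary: strict inequality
  f_eq <- scalar_field(g$mesh, rep(0.5, n))
  expect_equal(low_wss_mask(f_eq, 0.5)$area_fraction, 0)
  # half-area split (uniform tube: equal-area faces)
  vals <- rep(1, n); vals[seq_len(n / 2)] <- 0.2
  fr <- low_wss_mask(scalar_field(g$mesh, vals), 0.5)$area_fraction
  expect_equal(fr, 0.5, tolerance = 0.01)
})

test_that("similarity index satisfies its oracle cases", {
  g <- get_tiny_tube()
  n <- nrow(g$mesh$faces)
  vals <- rep(1, n); vals[1:20] <- 0.1
  mA <- low_wss_mask(scalar_field(g$mesh, vals), 0.5)
  expect_equal(similarity_index(mA, mA), 1)
  # disjoint non-empty masks
  v2 <- rep(1, n); v2[21:40] <- 0.1
  mB <- low_wss_mask(scalar_field(g$mesh, v2), 0.5)
  expect_equal(similarity_index(mA, mB), 0)
  # equal areas, half overlap: SI = 0.5 (uniform tube, equal-area faces)
  v3 <- rep(1, n); v3[11:30] <- 0.1
  mC <- low_wss_mask(scalar_field(g$mesh, v3), 0.5)
  expect_equal(similarity_index(mA, mC), 0.5, tolerance = 0.01)
  # symmetry
  expect_equal(similarity_index(mA, mC), similarity_index(mC, mA))
  # both empty: defined as 1, flagged
  mE <- low_wss_mask(scalar_field(g$mesh, rep(1, n)), 0.5)
  si <- similarity_index(mE, mE)
  expect_equal(as.numeric(si), 1)
  expect_true(attr(si, "both_empty"))
})
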