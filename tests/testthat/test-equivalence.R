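test_that("analytic relative error reproduces its closed form", {
  eps <- analytic_relative_error(1.25, 0.1)
  expect_equal(unname(eps["eps_min"]), (1 - (1.25 / 1.15)^3) * 100)
  expect_equal(unname(eps["eps_max"]), (1 - (1.25 / 1.35)^3) * 100)
  expect_equal(unname(analytic_relative_error(1.25, 0.1, rounded = TRUE)),
               c(-28, 21))
  expect_equal(unname(analytic_relative_error(1.25, 0)), c(0, 0))
  eps2 <- analytic_relative_error(1.25, 0.125)
  expect_equal(unname(eps2), c((1 - (1.25 / 1.125)^3) * 100,
                               (1 - (1.25 / 1.375)^3) * 100))
  expect_equal(unname(eps2), c(-37.2, 24.9), tolerance = 0.002)
  expect_error(analytic_relative_error(1, 1), "smaller than the radius")
})

test_that("cubic asymmetry: underestimation always hurts more", {
  set.seed(13)
  for (i in 1:20) {
    a <- runif(1, 0.8, 3)
    d <- runif(1, 0.01, 0.9) * a
    eps <- analytic_relative_error(a, d)
    expect_lt(eps["eps_min"], 0)
    expect_gt(eps["eps_max"], 0)
    expect_gt(abs(eps["eps_min"]), eps["eps_max"])
  }
})

test_that("margins derive from nominal levels and the conservative fraction", {
  expect_equal(derive_margin(1, 0.25), 0.25)
  expect_equal(derive_margin(0.2, 0.25), 0.05)
  expect_warning(m0 <- derive_margin(1, 0), "degenerate")
  expect_equal(m0, 0)
})

test_that("equivalence map classifies positions and aggregates per region", {
  region <- rep(c("proximal", "distal"), each = 8)
  profA <- data.frame(region = region, mean = rep(1, 16), area = rep(1, 16))
  # identical inputs: 100% everywhere present
  eq0 <- equivalence_map(profA, profA, margin = 0.25)
  expect_equal(unname(eq0$percent[c("proximal", "distal")]), c(100, 100))
  # uniform 0.3 Pa offset vs 0.25 margin: 0%
  profB <- profA; profB$mean <- profA$mean + 0.3
  eq1 <- equivalence_map(profA, profB, margin = 0.25)
  expect_equal(unname(eq1$percent[c("proximal", "distal")]), c(0, 0))
  # half the positions off by 0.1, half by 0.4, equal areas: 50% per region
  profC <- profA
  profC$mean <- profA$mean + rep(c(0.1, 0.4), 8)
  eq2 <- equivalence_map(profA, profC, margin = 0.25)
  expect_equal(unname(eq2$percent[c("proximal", "distal")]), c(50, 50))
  # swap-invariance
  eq3 <- equivalence_map(profC, profA, margin = 0.25)
  expect_equal(eq3$percent, eq2$percent)
  # boundary is excluded (strict inequality)
  profD <- profA; profD$mean <- profA$mean + 0.25
  expect_equal(unname(equivalence_map(profA, profD,
                                      margin = 0.25)$percent["proximal"]), 0)
})

test_that("TOST decides equivalence with exact degenerate handling", {
  # all-zero differences: equivalent with p ~ 0
  t0 <- tost_region(rep(0, 16), margin = 0.25)
  expect_true(t0$equivalent)
  expect_lt(t0$p_value, 0.05)
  # differences at the margin: cannot reject
  t1 <- tost_region(rep(0.25, 16), margin = 0.25)
  expect_false(t1$equivalent)
  expect_gte(t1$p_value, 0.05)
  # tight differences well inside the margin
  set.seed(21)
  t2 <- tost_region(rnorm(16, 0, 0.05), margin = 0.25)
  expect_true(t2$equivalent)
  expect_lt(t2$p_value, 0.001)
  # agreement with the textbook construction: p = max of two one-sided t tests
  d <- c(-0.1, 0.05, 0.02, -0.03, 0.08, 0, 0.04, -0.06)
  got <- tost_region(d, margin = 0.15)
  p_lo <- stats::t.test(d, mu = -0.15, alternative = "greater")$p.value
  p_hi <- stats::t.test(d, mu = 0.15, alternative = "less")$p.value
  expect_equal(got$p_value, max(p_lo, p_hi))
  expect_error(tost_region(c(0, 0), margin = 0.1), "at least 3")
})
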