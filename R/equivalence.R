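#' Analytic relative WSS error induced by a wall-position uncertainty
#'
#' The developed-flow WSS scales as `1/a^3`, so a reconstruction that
#' places the wall at `a' = a +/- delta` changes the computed WSS by
#' `eps = (1 - (a/a')^3) * 100` percent (flow, viscosity and profile shape
#' cancel in the ratio). Returns the two extremes: `eps_min` for an
#' underestimated radius (`a' = a - delta`, WSS overestimated, negative
#' sign) and `eps_max` for an overestimated radius. The asymmetry of the
#' cube makes `|eps_min| > eps_max` for any `delta > 0`.
#'
#' @param a nominal lumen radius (mm).
#' @param delta wall-position uncertainty (mm), `0 <= delta < a`. The
#'   default 0.1 mm is a typical angiographic resolution.
#' @param rounded round the extremes to integer percent.
#' @return Named vector `c(eps_min = ..., eps_max = ...)` in percent.
#' @examples
#' analytic_relative_error(1.25, 0.1, rounded = TRUE) # -28, 21
#' @export
analytic_relative_error <- function(a = 1.25, delta = 0.1, rounded = FALSE) {
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  check_number(delta, "delta", lower = 0)
  if (delta >= a)
    stop_config("delta = %g must be smaller than the radius a = %g", delta, a)
  eps <- function(a_prime) (1 - (a / a_prime)^3) * 100
  out <- c(eps_min = eps(a - delta), eps_max = eps(a + delta))
  if (rounded) out <- round(out)
  out
}

#' Derive an equivalence margin from a nominal metric value
#'
#' The margin is a conservative fraction of the nominal metric level:
#' with the default 25% relative-error allowance, a nominal proximal WSS
#' of 1 Pa gives the 0.25 Pa WSS/TAWSS margin, and a nominal peak
#' directional-mean OSI of 0.2 gives the 0.05 OSI margin.
#'
#' @param nominal_value nominal metric level (> 0; Pa for WSS/TAWSS,
#'   dimensionless for OSI).
#' @param conservative_fraction fraction of the nominal value, in (0, 1).
#' @return The margin, in the metric's units.
#' @examples
#' derive_margin(1)   # 0.25 Pa
#' derive_margin(0.2) # 0.05
#' @export
derive_margin <- function(nominal_value, conservative_fraction = 0.25) {
  check_number(nominal_value, "nominal_value", lower = 0, strict_lower = TRUE)
  check_number(conservative_fraction, "conservative_fraction",
               lower = 0, upper = 1, strict_upper = TRUE)
  if (conservative_fraction == 0)
    warning("zero conservative fraction yields a degenerate margin of 0")
  nominal_value * conservative_fraction
}

#' Per-position equivalence classification with regional percentages
#'
#' Classifies each position as equivalent when `|A - B| < margin` (strict
#' inequality) and reports the area-weighted percentage of equivalent
#' positions per region. Accepts either two clip-aligned 2D maps or two
#' [directional_means()] data frames of identical layout.
#'
#' @param profA,profB either two `map2d` objects (after [clip_align()]) or
#'   two directional-mean data frames with matching `region` columns.
#' @param margin equivalence margin (same units as the values).
#' @param alpha significance level forwarded to the per-region TOST.
#' @return An object of class `equivalence_result`: logical `equivalent`
#'   per position, `percent` per region, per-region TOST `p_values`, and
#'   the margin/alpha used.
#' @export
equivalence_map <- function(profA, profB, margin, alpha = 0.05) {
  check_number(margin, "margin", lower = 0, strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (inherits(profA, "map2d") && inherits(profB, "map2d")) {
    if (!all(dim(profA$values) == dim(profB$values)) ||
        !identical(profA$valid, profB$valid))
      stop_config("maps must be clip-aligned (same shape and validity)")
    ok <- profA$valid
    diffs <- (profA$values - profB$values)[ok]
    w <- ((profA$area + profB$area) / 2)[ok]
    region <- matrix(profA$region, nrow(profA$values), ncol(profA$values))[ok]
  } else {
    if (nrow(profA) != nrow(profB) ||
        !identical(as.character(profA$region), as.character(profB$region)))
      stop_config("directional-mean profiles have mismatched shape or regions")
    ok <- !is.na(profA$mean) & !is.na(profB$mean)
    diffs <- (profA$mean - profB$mean)[ok]
    w <- ((profA$area + profB$area) / 2)[ok]
    region <- as.character(profA$region)[ok]
  }
  equivalent <- abs(diffs) < margin
  regions <- c("proximal", "stenosis", "distal")
  percent <- stats::setNames(rep(NA_real_, 3), regions)
  p_values <- stats::setNames(rep(NA_real_, 3), regions)
  for (reg in regions) {
    in_reg <- region == reg & !is.na(region)
    if (!any(in_reg)) next
    percent[reg] <- 100 * sum(w[in_reg & equivalent]) / sum(w[in_reg])
    if (sum(in_reg) >= 3)
      p_values[reg] <- tost_region(diffs[in_reg], margin, alpha)$p_value
  }
  structure(list(equivalent = equivalent, diffs = diffs, weights = w,
                 region = region, percent = percent, p_values = p_values,
                 margin = margin, alpha = alpha),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf("Equivalence at margin %g (alpha %g):\n", x$margin, x$alpha))
  for (reg in names(x$percent)) {
    cat(sprintf("  %-9s %5.1f%% equivalent (TOST p = %s)\n", reg,
                x$percent[reg],
                ifelse(is.na(x$p_values[reg]), "NA",
                       format.pval(x$p_values[reg], digits = 3))))
  }
  invisible(x)
}

#' Two one-sided tests (TOST) for equivalence of paired differences
#'
#' Realizes the margin-based noninferiority/equivalence test: the null
#' hypothesis that the mean absolute difference exceeds the margin is
#' rejected when both one-sided t-tests (H0: mean <= -margin and
#' H0: mean >= +margin) reject. The reported p-value is the larger of the
#' two one-sided p-values; equivalence is declared when `p < alpha`.
#' Zero-variance samples are decided exactly on the mean alone.
#'
#' @param diffs per-position paired differences within one region (n >= 3).
#' @param margin equivalence margin (> 0), same units as `diffs`.
#' @param alpha significance level.
#' @return List with `p_value`, `equivalent`, `mean_diff`, `n`.
#' @examples
#' tost_region(rep(0, 16), margin = 0.25)$equivalent # TRUE
#' @export
tost_region <- function(diffs, margin, alpha = 0.05) {
  check_number(margin, "margin", lower = 0, strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  if (n < 3) stop_config("TOST needs at least 3 positions, got %d", n)
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (s <= .Machine$double.eps) {
    p <- if (abs(m) < margin) 0 else 1
    return(list(p_value = p, equivalent = abs(m) < margin, mean_diff = m, n = n))
  }
  se <- s / sqrt(n)
  p_lower <- stats::pt((m + margin) / se, df = n - 1, lower.tail = FALSE)
  p_upper <- stats::pt((m - margin) / se, df = n - 1, lower.tail = TRUE)
  p <- max(p_lower, p_upper)
  list(p_value = p, equivalent = p < alpha, mean_diff = m, n = n)
}
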