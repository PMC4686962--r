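#' Pulsatile coronary inflow waveform
#'
#' Builds a diastole-dominant, strictly positive two-lobe flow waveform:
#' a small systolic lobe followed by a larger diastolic lobe on top of a
#' positive baseline, sampled on a uniform periodic grid and rescaled so
#' its mean equals `q_mean` exactly. The default cycle is 0.8 s in 100
#' steps; lobe weights are free shape parameters (both zero gives a
#' constant waveform).
#'
#' @param T cycle period (s).
#' @param n_steps number of uniform samples per cycle.
#' @param q_mean cycle-averaged flow (ml/s).
#' @param systolic_fraction fraction of the cycle occupied by systole.
#' @param systolic_weight,diastolic_weight lobe amplitudes relative to the
#'   baseline (dimensionless, >= 0).
#' @param baseline positive baseline level (dimensionless, > 0).
#' @return An object of class `flow_series` with fields `T`, `n_steps`,
#'   `t`, `q` (ml/s) and `q_mean`.
#' @examples
#' fl <- coronary_waveform()
#' mean(fl$q) # == q_mean
#' @export
coronary_waveform <- function(T = 0.8, n_steps = 100, q_mean = 0.368,
                              systolic_fraction = 0.35,
                              systolic_weight = 0.5,
                              diastolic_weight = 1.4,
                              baseline = 0.45) {
  check_number(T, "T", lower = 0, strict_lower = TRUE)
  if (n_steps < 2) stop_config("n_steps must be >= 2")
  check_number(q_mean, "q_mean", lower = 0, strict_lower = TRUE)
  check_number(systolic_fraction, "systolic_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(systolic_weight, "systolic_weight", lower = 0)
  check_number(diastolic_weight, "diastolic_weight", lower = 0)
  check_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  t <- T * (seq_len(n_steps) - 1L) / n_steps
  ts <- systolic_fraction * T
  hann <- function(u) 0.5 * (1 - cos(2 * pi * u))  # u in [0,1]
  shape <- baseline +
    systolic_weight * ifelse(t < ts, hann(t / ts), 0) +
    diastolic_weight * ifelse(t >= ts, hann((t - ts) / (T - ts)), 0)
  if (any(shape <= 0))
    stop_config("waveform shape parameters produce non-positive flow")
  q <- shape * (q_mean / mean(shape))
  flow_series(T = T, t = t, q = q)
}

#' Construct a flow series from samples
#'
#' @param T cycle period (s).
#' @param t uniform time samples in `[0, T)` (s).
#' @param q flow at each sample (ml/s), strictly positive.
#' @return A `flow_series`.
#' @export
flow_series <- function(T, t, q) {
  if (length(t) != length(q) || length(q) < 1L)
    stop_config("'t' and 'q' must be equal-length, non-empty")
  if (any(q <= 0)) stop_config("coronary inflow must be positive at all samples")
  structure(list(T = T, n_steps = length(q), t = as.numeric(t),
                 q = as.numeric(q), q_mean = mean(q)),
            class = "flow_series")
}

#' Steady flow (single time sample)
#' @param q_mean flow (ml/s).
#' @return A single-sample `flow_series` encoding a steady solution.
#' @export
steady_flow <- function(q_mean = 0.368) {
  check_number(q_mean, "q_mean", lower = 0, strict_lower = TRUE)
  flow_series(T = 1, t = 0, q = q_mean)
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf("Flow series: %d step(s) over %g s, mean %g ml/s, range %g-%g ml/s\n",
              x$n_steps, x$T, x$q_mean, min(x$q), max(x$q)))
  invisible(x)
}

#' Carreau viscosity model for blood
#'
#' `mu = mu_inf + (mu0 - mu_inf) * (1 + (lambda * shear)^2)^((n - 1)/2)`.
#' Default parameters are the standard Carreau fit for blood
#' (zero-shear 0.056 Pa s, infinite-shear 0.00345 Pa s, relaxation 3.313 s,
#' power index 0.3568) with density 1060 kg/m^3.
#'
#' @param mu0 zero-shear viscosity (Pa s).
#' @param mu_inf infinite-shear viscosity (Pa s).
#' @param lambda relaxation time (s).
#' @param n_exp power-law index, in (0, 1).
#' @param rho fluid density (kg/m^3).
#' @return An object of class `viscosity_model`.
#' @export
viscosity_model <- function(mu0 = 0.056, mu_inf = 0.00345, lambda = 3.313,
                            n_exp = 0.3568, rho = 1060) {
  check_number(mu0, "mu0", lower = 0, strict_lower = TRUE)
  check_number(mu_inf, "mu_inf", lower = 0, strict_lower = TRUE)
  if (mu0 <= mu_inf) stop_config("mu0 must exceed mu_inf")
  check_number(lambda, "lambda", lower = 0, strict_lower = TRUE)
  check_number(n_exp, "n_exp", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(rho, "rho", lower = 0, strict_lower = TRUE)
  structure(list(mu0 = mu0, mu_inf = mu_inf, lambda = lambda,
                 n_exp = n_exp, rho = rho), class = "viscosity_model")
}

#' Evaluate Carreau viscosity at a shear rate
#'
#' @param shear_rate shear rate (1/s), >= 0; vectorized.
#' @param model a [viscosity_model()].
#' @return Dynamic viscosity (Pa s).
#' @examples
#' carreau_viscosity(0)    # zero-shear limit, 0.056
#' carreau_viscosity(100)  # ~4.7e-3
#' @export
carreau_viscosity <- function(shear_rate, model = viscosity_model()) {
  stopifnot(inherits(model, "viscosity_model"))
  if (any(shear_rate < 0)) stop_config("shear_rate must be >= 0")
  model$mu_inf + (model$mu0 - model$mu_inf) *
    (1 + (model$lambda * shear_rate)^2)^((model$n_exp - 1) / 2)
}

#' Diameter-based outflow split at a bifurcation
#'
#' `fraction_i = d_i^k / (d_main^k + d_side^k)`; the default exponent 3 is
#' the Murray-law scaling commonly used to set bifurcation outflow ratios.
#'
#' @param d_main,d_side outlet diameters (mm, any consistent unit).
#' @param exponent positive scaling exponent.
#' @return Named numeric vector `c(main = ..., side = ...)` summing to 1.
#' @examples
#' split_outflow(2, 1, exponent = 3) # 8/9, 1/9
#' @export
split_outflow <- function(d_main, d_side, exponent = 3) {
  check_number(d_main, "d_main", lower = 0, strict_lower = TRUE)
  check_number(d_side, "d_side", lower = 0, strict_lower = TRUE)
  check_number(exponent, "exponent", lower = 0, strict_lower = TRUE)
  pm <- d_main^exponent
  ps <- d_side^exponent
  c(main = pm / (pm + ps), side = ps / (pm + ps))
}

#' Analytic wall shear stress of a developed tube flow
#'
#' For a velocity profile of shape exponent `beta` (2 = parabolic
#' Poiseuille, larger = blunter), the wall shear stress in a straight tube
#' is `tau = q * (beta + 2) * mu / (pi * a^3)`. With `beta = 2` this is the
#' classic Poiseuille wall shear `4 mu q / (pi a^3)`.
#'
#' @param q volumetric flow (m^3/s).
#' @param beta velocity-profile shape exponent (>= 2).
#' @param mu dynamic viscosity (Pa s).
#' @param a lumen radius (m), > 0.
#' @return Wall shear stress (Pa); vectorized over any argument.
#' @examples
#' # representative proximal coronary conditions: ~0.84 Pa
#' a <- 1.25e-3; q <- 0.15 / 2 * pi * a^2
#' poiseuille_wss(q, 2, 3.5e-3, a)
#' @export
poiseuille_wss <- function(q, beta = 2, mu = 3.5e-3, a = 1.25e-3) {
  if (any(a <= 0)) stop_config("radius 'a' must be positive")
  if (any(q < 0) || any(mu <= 0) || any(beta < 2))
    stop_config("q must be >= 0, mu > 0, beta >= 2")
  q * (beta + 2) * mu / (pi * a^3)
}

#' Womersley number diagnostic
#'
#' `alpha = a * sqrt(2 * pi / T * rho / mu)`. Reported as a diagnostic for
#' the quasi-steady surrogate: small values justify quasi-steady profiles.
#'
#' @param a radius (m).
#' @param T cycle period (s).
#' @param rho density (kg/m^3).
#' @param mu viscosity (Pa s).
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(a = 1.25e-3, T = 0.8, rho = 1060, mu = 3.5e-3) {
  a * sqrt(2 * pi / T * rho / mu)
}

#' Surrogate flow-model parameters
#'
#' Parameters of the analytic quasi-steady surrogate used in place of a
#' CFD solver: velocity-profile shape, inlet peak velocity, and the
#' post-stenotic recirculation crescent (length scaling linear in the jet
#' Reynolds number, as for laminar expansions; angular extent; retrograde
#' magnitude factor).
#'
#' @param beta velocity-profile shape exponent (>= 2; 2 = parabolic).
#' @param v_peak_inlet inlet peak velocity (m/s); 0.15 m/s is a
#'   representative resting coronary value and sets the default flows.
#' @param recirc_length_coeff dimensionless coefficient of the laminar
#'   sudden-expansion correlation: reattachment length
#'   `L_r = coeff * Re_jet * h` with step height `h = a_dist - a_throat`.
#'   The default 0.088 is the standard laminar backward-facing-step slope;
#'   step-height scaling makes the recirculation zone sensitive to throat
#'   reconstruction errors and vanish without a stenosis.
#' @param recirc_angular_extent angular width of the retrograde crescent
#'   (deg), centered opposite the side branch.
#' @param recirc_magnitude_factor retrograde |WSS| relative to the local
#'   antegrade value, in (0, 1).
#' @return An object of class `surrogate_flow_params`.
#' @export
surrogate_flow_params <- function(beta = 2, v_peak_inlet = 0.15,
                                  recirc_length_coeff = 0.088,
                                  recirc_angular_extent = 200,
                                  recirc_magnitude_factor = 0.35) {
  check_number(beta, "beta", lower = 2)
  check_number(v_peak_inlet, "v_peak_inlet", lower = 0, strict_lower = TRUE)
  check_number(recirc_length_coeff, "recirc_length_coeff", lower = 0,
               strict_lower = TRUE)
  check_number(recirc_angular_extent, "recirc_angular_extent", lower = 0,
               upper = 360, strict_lower = TRUE)
  check_number(recirc_magnitude_factor, "recirc_magnitude_factor", lower = 0,
               upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  structure(list(beta = beta, v_peak_inlet = v_peak_inlet,
                 recirc_length_coeff = recirc_length_coeff,
                 recirc_angular_extent = recirc_angular_extent,
                 recirc_magnitude_factor = recirc_magnitude_factor),
            class = "surrogate_flow_params")
}

#' Mean inflow implied by a parabolic inlet profile
#'
#' `q = v_peak / 2 * pi * a^2`, returned in ml/s for a radius in mm.
#' @param a_mm inlet radius (mm).
#' @param v_peak peak velocity (m/s).
#' @return Flow in ml/s.
#' @export
inlet_flow_from_peak_velocity <- function(a_mm = 1.25, v_peak = 0.15) {
  a <- a_mm * 1e-3
  (v_peak / 2) * pi * a^2 * 1e6
}
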