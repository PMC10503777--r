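#' cvstate: mechanistic cardiovascular state inference
#'
#' Lumped-parameter model of the systemic circulation in pressure form, with
#' autonomic control (baroreflex plus an independent drive), a forward
#' simulator of shock scenarios, a beat-resolved waveform synthesizer, a
#' feature-extraction pipeline, and a constrained multi-start estimator of the
#' fifteen hidden physiological parameters.
#'
#' @keywords internal
"_PACKAGE"

## Baroreflex sensitivity (1/mmHg), fixed across the package.
KB_DEFAULT <- 0.1838

## Gain of the sigmoids combining autonomic components.
SIGMOID_GAIN <- 3.3

## Minimal admissible arterial-venous gradient (mmHg) inside the
## pulse-pressure relation; below this the model regime is violated.
MIN_AV_GRADIENT <- 0.5

.assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`", name, "` must be finite numeric", call. = FALSE)
  invisible(x)
}

#' Baroreflex activation
#'
#' Autonomic feedback component driven by the deviation of arterial pressure
#' from its set point: `S_b = 1 - 1 / (1 + exp(-k_b (P_a - P_set)))`.
#' Decreases monotonically with arterial pressure, taking values in (0, 1)
#' with `S_b = 0.5` at the set point.
#'
#' @param p_a Arterial pressure, mmHg. Vectorized.
#' @param p_set Baroreflex set point, mmHg.
#' @param k_b Baroreflex sensitivity, 1/mmHg (> 0).
#' @return Activation in (0, 1), same length as `p_a`.
#' @export
#' @examples
#' baroreflex_activation(50, 50)        # 0.5 at the set point
#' baroreflex_activation(60, 50)        # < 0.5: high pressure withdraws tone
baroreflex_activation <- function(p_a, p_set, k_b = KB_DEFAULT) {
  .assert_finite(p_a, "p_a"); .assert_finite(p_set, "p_set")
  .assert_finite(k_b, "k_b")
  if (k_b <= 0) stop("`k_b` must be positive", call. = FALSE)
  1 - stats::plogis(k_b * (p_a - p_set))
}

#' Total autonomic activation
#'
#' Combines the baroreflex `s_b` and the pressure-independent drive `s` into
#' one activation: `S_tot = 1 / (1 + exp(-3.3 (S_b + S - 1)))`, strictly in
#' (0, 1), approximately the mean of its two inputs, and equal to 0.5 when
#' they sum to one.
#'
#' @param s_b Baroreflex activation in \[0, 1\]. Vectorized.
#' @param s Independent autonomic drive in \[0, 1\]. Vectorized.
#' @return Total activation in (0, 1).
#' @export
total_autonomic_activation <- function(s_b, s) {
  .assert_finite(s_b, "s_b"); .assert_finite(s, "s")
  if (any(s_b < 0 | s_b > 1)) stop("`s_b` must lie in [0, 1]", call. = FALSE)
  if (any(s < 0 | s > 1)) stop("`s` must lie in [0, 1]", call. = FALSE)
  stats::plogis(SIGMOID_GAIN * (s_b + s - 1))
}

#' Heart rate from autonomic activation
#'
#' Linear interpolation between the subject's minimal and maximal heart
#' rates: `Hr = Hr_min + (Hr_max - Hr_min) S_tot`.
#'
#' @param s_tot Total autonomic activation in \[0, 1\]. Vectorized.
#' @param hr_min,hr_max Heart-rate range, beats/min, `hr_min < hr_max`.
#' @return Heart rate, beats/min.
#' @export
heart_rate <- function(s_tot, hr_min, hr_max) {
  .assert_finite(s_tot, "s_tot")
  if (any(s_tot < 0 | s_tot > 1)) stop("`s_tot` must lie in [0, 1]", call. = FALSE)
  if (!(hr_min < hr_max)) stop("`hr_min` must be < `hr_max`", call. = FALSE)
  hr_min + (hr_max - hr_min) * s_tot
}

#' Vascular resistance modulation
#'
#' Fraction of the resistance range recruited by the total autonomic
#' activation and the non-autonomic modulation `M_SVR`:
#' `R_mod = 1 / (1 + exp(-3.3 (S_tot + M_SVR)))`, in (0, 1).
#'
#' @param s_tot Total autonomic activation in \[0, 1\]. Vectorized.
#' @param m_svr Non-autonomic resistance modulation in \[-1, 1\]. Vectorized.
#' @return Modulation fraction in (0, 1).
#' @export
resistance_modulation <- function(s_tot, m_svr) {
  .assert_finite(s_tot, "s_tot"); .assert_finite(m_svr, "m_svr")
  if (any(s_tot < 0 | s_tot > 1)) stop("`s_tot` must lie in [0, 1]", call. = FALSE)
  if (any(m_svr < -1 | m_svr > 1)) stop("`m_svr` must lie in [-1, 1]", call. = FALSE)
  stats::plogis(SIGMOID_GAIN * (s_tot + m_svr))
}

#' Peripheral resistance
#'
#' `R = R_min + (R_max - R_min) R_mod`. Works identically for the physical
#' resistance (mmHg s/ml) and its scaled form (s).
#'
#' @param r_mod Modulation fraction in (0, 1).
#' @param r_min,r_max Resistance range, `r_min < r_max`.
#' @return Resistance in the same units as the range.
#' @export
peripheral_resistance <- function(r_mod, r_min, r_max) {
  if (!(r_min < r_max)) stop("`r_min` must be < `r_max`", call. = FALSE)
  r_min + (r_max - r_min) * r_mod
}

#' Pulse pressure from contractility and filling
#'
#' The one-chamber heart ejects a stroke volume proportional to the relative
#' contractility and the ventricular filling (approximated by the venous
#' pressure) against the arterial-venous gradient:
#' `P_p = K(S_tot) P_v / (P_a - P_v)` with
#' `K = K_min + (K_max - K_min) S_tot` the relative contractility (mmHg).
#' The relation degenerates as `P_a` approaches `P_v`; gradients below
#' 0.5 mmHg raise an error rather than extrapolate.
#'
#' @param s_tot Total autonomic activation in \[0, 1\]. Vectorized.
#' @param k_min,k_max Relative contractility range, mmHg, `k_min < k_max`.
#' @param p_a,p_v Arterial and venous pressures, mmHg, `p_a > p_v >= 0`.
#' @return Pulse pressure, mmHg (nonnegative).
#' @export
pulse_pressure_model <- function(s_tot, k_min, k_max, p_a, p_v) {
  .assert_finite(p_a, "p_a"); .assert_finite(p_v, "p_v")
  if (!(k_min < k_max)) stop("`k_min` must be < `k_max`", call. = FALSE)
  if (any(p_v < 0)) stop("`p_v` must be nonnegative", call. = FALSE)
  if (any(p_a - p_v < MIN_AV_GRADIENT))
    stop("arterial-venous gradient below ", MIN_AV_GRADIENT,
         " mmHg: pulse-pressure relation is singular", call. = FALSE)
  k <- k_min + (k_max - k_min) * s_tot
  k * p_v / (p_a - p_v)
}

#' Linear autonomic drives with range clipping
#'
#' Per-segment linear parameterization of the independent autonomic drive and
#' the non-autonomic resistance modulation:
#' `S(t) = S_const + S_slope t` clipped to \[0, 1\] and
#' `M_SVR(t) = M_const + M_slope t` clipped to \[-1, 1\]. Time is measured
#' from the segment (or scenario) origin.
#'
#' @param t Time since segment start, s. Vectorized.
#' @param s_const,s_slope Intercept (dimensionless) and slope (1/s) of `S`.
#' @param m_const,m_slope Intercept and slope (1/s) of `M_SVR`.
#' @return List with components `s` and `m_svr`, each the length of `t`.
#' @export
autonomic_drives <- function(t, s_const, s_slope, m_const, m_slope) {
  list(
    s = pmin(1, pmax(0, s_const + s_slope * t)),
    m_svr = pmin(1, pmax(-1, m_const + m_slope * t))
  )
}

#' Pressure-form model derivatives
#'
#' Right-hand side of the two pressure ODEs. Arterial: inflow from the heart
#' (heart rate times pulse pressure, the stroke volume over arterial
#' compliance) minus the resistive outflow,
#' `dP_a/dt = Hr P_p - (P_a - P_v) / (C_a R)` (Hr in beats/s).
#' Venous: volume bookkeeping
#' `dP_v/dt = (I_ex - C_a dP_a/dt + dV_v0 dS_tot/dt) / C_v`, where
#' `dS_tot/dt` is evaluated analytically by the chain rule through the
#' baroreflex (explicit, since `dP_a/dt` does not depend on `dP_v/dt`).
#'
#' @param state List or named vector with `p_a` and `p_v` (mmHg).
#' @param params Physical parameter set from [physical_params()].
#' @param drives List with instantaneous drive values `s`, `m_svr`,
#'   `i_ex` (ml/s) and their time slopes `s_slope`, (optionally) unused
#'   elsewhere.
#' @return List with `dp_a`, `dp_v` (mmHg/s) and the diagnostic autonomic
#'   state (`s_b`, `s_tot`, `hr`, `r`, `p_p`, `ds_tot`).
#' @export
pressure_derivatives <- function(state, params, drives) {
  p_a <- state[["p_a"]]; p_v <- state[["p_v"]]
  if (!is.finite(p_a) || !is.finite(p_v))
    stop("non-finite pressures", call. = FALSE)
  if (p_a - p_v < MIN_AV_GRADIENT)
    stop("arterial-venous gradient collapsed (P_a - P_v < ",
         MIN_AV_GRADIENT, " mmHg)", call. = FALSE)

  s_b <- baroreflex_activation(p_a, params$p_set, params$k_b)
  s_tot <- total_autonomic_activation(s_b, drives$s)
  hr_bps <- heart_rate(s_tot, params$hr_min, params$hr_max) / 60
  r_mod <- resistance_modulation(s_tot, drives$m_svr)
  r <- peripheral_resistance(r_mod, params$r_min, params$r_max)
  p_p <- pulse_pressure_model(s_tot, params$k_min, params$k_max, p_a, p_v)

  dp_a <- hr_bps * p_p - (p_a - p_v) / (params$c_a * r)

  ## chain rule: dS_tot/dt = g St(1-St) (dS_b/dt + dS/dt),
  ## dS_b/dt = -k_b S_b (1 - S_b) dP_a/dt
  ds_b <- -params$k_b * s_b * (1 - s_b) * dp_a
  ds <- if (is.null(drives$s_slope)) 0 else drives$s_slope
  ds_tot <- SIGMOID_GAIN * s_tot * (1 - s_tot) * (ds_b + ds)

  dp_v <- (drives$i_ex - params$c_a * dp_a + params$d_v_v0 * ds_tot) /
    params$c_v

  list(dp_a = dp_a, dp_v = dp_v,
       s_b = s_b, s_tot = s_tot, hr = hr_bps * 60, r = r, p_p = p_p,
       ds_tot = ds_tot)
}
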