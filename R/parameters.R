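#' Patient metadata
#'
#' The only prior information the estimator uses about a subject: age (to
#' select the normative bracket for pressures and heart rates) and weight
#' (to scale blood volume).
#'
#' @param age_years Age in years (fractions allowed; a neonate is ~0.02).
#' @param weight_kg Body mass, kg (> 0).
#' @return Object of class `patient_meta`.
#' @export
#' @examples
#' patient_meta(age_years = 1 / 24, weight_kg = 3.5)  # two-week-old neonate
patient_meta <- function(age_years, weight_kg) {
  if (!is.numeric(age_years) || length(age_years) != 1 || age_years < 0)
    stop("`age_years` must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(weight_kg) || length(weight_kg) != 1 || weight_kg <= 0)
    stop("`weight_kg` must be a single positive number", call. = FALSE)
  structure(list(age_years = age_years, weight_kg = weight_kg),
            class = "patient_meta")
}

#' @export
print.patient_meta <- function(x, ...) {
  cat(sprintf("patient: age %.2f y, weight %.1f kg\n",
              x$age_years, x$weight_kg))
  invisible(x)
}

#' Physical (simulation) parameter set
#'
#' Parameters of the circulation in native units, as used by the forward
#' simulator. Contractility appears only through the relative contractility
#' range `k_min`/`k_max` (mmHg): ventricular contractility times ventricular
#' compliance over arterial compliance, which is all the pressure-form
#' equations need. Defaults are the artificial-neonate simulation set:
#' set point 50 mmHg, heart rate 100-180 beats/min, relative contractility
#' 200-800 mmHg, resistance 0.8-1.8 mmHg s/ml, arterial compliance
#' 0.45 ml/mmHg, venous compliance 10 ml/mmHg, recruitable unstressed venous
#' volume 65 ml.
#'
#' @param p_set Baroreflex set point, mmHg.
#' @param hr_min,hr_max Heart-rate range, beats/min.
#' @param k_min,k_max Relative contractility range, mmHg.
#' @param r_min,r_max Peripheral resistance range, mmHg s/ml.
#' @param c_a,c_v Arterial and venous compliances, ml/mmHg.
#' @param d_v_v0 Difference between maximal and minimal unstressed venous
#'   volume, ml.
#' @param k_b Baroreflex sensitivity, 1/mmHg.
#' @return Object of class `physical_params`.
#' @export
physical_params <- function(p_set = 50, hr_min = 100, hr_max = 180,
                            k_min = 200, k_max = 800,
                            r_min = 0.8, r_max = 1.8,
                            c_a = 0.45, c_v = 10, d_v_v0 = 65,
                            k_b = KB_DEFAULT) {
  p <- list(p_set = p_set, hr_min = hr_min, hr_max = hr_max,
            k_min = k_min, k_max = k_max, r_min = r_min, r_max = r_max,
            c_a = c_a, c_v = c_v, d_v_v0 = d_v_v0, k_b = k_b)
  stopifnot(all(vapply(p, is.numeric, logical(1))))
  if (c_a <= 0 || c_v <= 0 || d_v_v0 < 0)
    stop("compliances must be positive, `d_v_v0` nonnegative", call. = FALSE)
  if (!(hr_min < hr_max) || !(r_min < r_max) || !(k_min < k_max))
    stop("parameter ranges must have min < max", call. = FALSE)
  if (r_min <= 0 || k_min <= 0)
    stop("resistances and contractilities must be positive", call. = FALSE)
  structure(p, class = "physical_params")
}

#' @export
print.physical_params <- function(x, ...) {
  cat("physical cardiovascular parameters:\n")
  cat(sprintf("  P_set %.1f mmHg | Hr %g-%g bpm | K %g-%g mmHg\n",
              x$p_set, x$hr_min, x$hr_max, x$k_min, x$k_max))
  cat(sprintf("  R %g-%g mmHg.s/ml | C_a %g, C_v %g ml/mmHg | dV_v0 %g ml\n",
              x$r_min, x$r_max, x$c_a, x$c_v, x$d_v_v0))
  invisible(x)
}

#' Scaled (estimable) parameter set
#'
#' The fifteen hidden parameters the estimator infers, in the scaled
#' pressure-form units that are identifiable from pressure observables alone:
#' compliances relative to the arterial compliance, volumes and volume rates
#' divided by the arterial compliance (hence in mmHg and mmHg/s), and
#' resistances multiplied by `alpha_rc * C_a` (hence in s, identified up to
#' the pulse-contour scale `alpha_rc`).
#'
#' @param p_set Baroreflex set point, mmHg.
#' @param c_v_rel Venous over arterial compliance (dimensionless).
#' @param d_v_v0_rel Recruitable unstressed venous volume over arterial
#'   compliance, mmHg.
#' @param i_ex_rel Intravascular volume change rate over arterial compliance,
#'   mmHg/s (signed; negative while bleeding).
#' @param hr_min,hr_max Heart-rate range, beats/min.
#' @param r_min_scaled,r_max_scaled Scaled resistance range, s.
#' @param k_min_rel,k_max_rel Relative contractility range, mmHg.
#' @param s_const,s_slope Independent autonomic drive intercept and slope (1/s).
#' @param m_const,m_slope Non-autonomic resistance modulation intercept and
#'   slope (1/s).
#' @param alpha_rc Pulse-contour resistance scale (dimensionless).
#' @param k_b Baroreflex sensitivity, 1/mmHg (fixed, not estimated).
#' @return Object of class `scaled_params` (named list of the 15 parameters
#'   plus `k_b`).
#' @export
scaled_params <- function(p_set, c_v_rel, d_v_v0_rel, i_ex_rel,
                          hr_min, hr_max, r_min_scaled, r_max_scaled,
                          k_min_rel, k_max_rel,
                          s_const, s_slope, m_const, m_slope,
                          alpha_rc, k_b = KB_DEFAULT) {
  p <- list(p_set = p_set, c_v_rel = c_v_rel, d_v_v0_rel = d_v_v0_rel,
            i_ex_rel = i_ex_rel, hr_min = hr_min, hr_max = hr_max,
            r_min_scaled = r_min_scaled, r_max_scaled = r_max_scaled,
            k_min_rel = k_min_rel, k_max_rel = k_max_rel,
            s_const = s_const, s_slope = s_slope,
            m_const = m_const, m_slope = m_slope,
            alpha_rc = alpha_rc, k_b = k_b)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && is.finite(v),
                       logical(1))))
  if (!(hr_min < hr_max) || !(r_min_scaled < r_max_scaled) ||
      !(k_min_rel < k_max_rel))
    stop("parameter ranges must have min < max", call. = FALSE)
  if (c_v_rel <= 0 || r_min_scaled <= 0 || k_min_rel <= 0 || alpha_rc <= 0)
    stop("scaled compliances, resistances, contractilities and alpha_rc ",
         "must be positive", call. = FALSE)
  if (s_const < 0 || s_const > 1)
    stop("`s_const` must lie in [0, 1]", call. = FALSE)
  if (m_const < -1 || m_const > 1)
    stop("`m_const` must lie in [-1, 1]", call. = FALSE)
  structure(p, class = "scaled_params")
}

#' @export
print.scaled_params <- function(x, ...) {
  cat("scaled model parameters (15 estimable):\n")
  cat(sprintf("  P_set %.1f | C~v %.2f | dV~v0 %.1f mmHg | I~ex %.4f mmHg/s\n",
              x$p_set, x$c_v_rel, x$d_v_v0_rel, x$i_ex_rel))
  cat(sprintf("  Hr %g-%g bpm | R~ %.3f-%.3f s | K~ %.0f-%.0f mmHg\n",
              x$hr_min, x$hr_max, x$r_min_scaled, x$r_max_scaled,
              x$k_min_rel, x$k_max_rel))
  cat(sprintf("  S %.2f %+.2e/s | M %.2f %+.2e/s | alpha_RC %.2f\n",
              x$s_const, x$s_slope, x$m_const, x$m_slope, x$alpha_rc))
  invisible(x)
}

## Canonical ordering of the 15 estimable parameters.
PARAM_NAMES <- c("p_set", "c_v_rel", "d_v_v0_rel", "i_ex_rel",
                 "hr_min", "hr_max", "r_min_scaled", "r_max_scaled",
                 "k_min_rel", "k_max_rel",
                 "s_const", "s_slope", "m_const", "m_slope", "alpha_rc")

#' Convert physical to scaled parameters
#'
#' Divides volumes and compliances by the arterial compliance and multiplies
#' resistances by `alpha_rc * C_a`, producing the parameterization in which
#' the model is identifiable from pressure data. The drive parameters
#' (`s_*`, `m_*`) and the volume rate are supplied by the caller since in a
#' simulation they belong to the scenario rather than the subject.
#'
#' @param params [physical_params()] object.
#' @param i_ex Intravascular volume change rate, ml/s.
#' @param s_const,s_slope,m_const,m_slope Linear drive parameters.
#' @param alpha_rc Pulse-contour resistance scale.
#' @return A [scaled_params()] object.
#' @export
as_scaled_params <- function(params, i_ex = 0, s_const = 0.2, s_slope = 0,
                             m_const = 0, m_slope = 0, alpha_rc = 1) {
  stopifnot(inherits(params, "physical_params"))
  scaled_params(
    p_set = params$p_set,
    c_v_rel = params$c_v / params$c_a,
    d_v_v0_rel = params$d_v_v0 / params$c_a,
    i_ex_rel = i_ex / params$c_a,
    hr_min = params$hr_min, hr_max = params$hr_max,
    r_min_scaled = alpha_rc * params$c_a * params$r_min,
    r_max_scaled = alpha_rc * params$c_a * params$r_max,
    k_min_rel = params$k_min, k_max_rel = params$k_max,
    s_const = s_const, s_slope = s_slope,
    m_const = m_const, m_slope = m_slope,
    alpha_rc = alpha_rc, k_b = params$k_b)
}
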