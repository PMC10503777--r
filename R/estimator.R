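## Arterial compliance per kg bracketing the pediatric-to-adult range,
## ml/(mmHg kg); used to convert volume bounds to pressure units.
C_MIN_PER_KG <- 0.02
C_MAX_PER_KG <- 0.15

.age_bracket <- function(table, age_months) {
  for (row in table) if (age_months < row$upto) return(row$range)
  table[[length(table)]]$range
}

#' Physiological bounds for the fifteen estimable parameters
#'
#' Builds the box constraints of the estimation problem from patient age and
#' weight. Set-point and heart-rate brackets follow pediatric normative
#' percentiles by age; volume-derived bounds use a per-kg blood volume
#' (100 ml/kg up to 3 months of age, 75 ml/kg thereafter), an
#' unstressed-venous-reserve fraction of 10-30% of blood volume, and a
#' volume-change rate capped at 25% of blood volume per hour, all divided by
#' the arterial-compliance-per-kg range so that weight cancels in the scaled
#' parameterization.
#'
#' @param meta A [patient_meta()].
#' @return A `param_bounds` data frame with rows in canonical parameter
#'   order and columns `lo`, `hi`.
#' @export
#' @examples
#' build_bounds(patient_meta(age_years = 0.02, weight_kg = 3.5))
build_bounds <- function(meta) {
  stopifnot(inherits(meta, "patient_meta"))
  am <- meta$age_years * 12

  p_set <- .age_bracket(list(
    list(upto = 1, range = c(42, 73)), list(upto = 3, range = c(44, 76)),
    list(upto = 6, range = c(52, 80)), list(upto = 12, range = c(52, 86)),
    list(upto = 36, range = c(56, 88)), list(upto = 72, range = c(55, 83)),
    list(upto = 108, range = c(58, 87)), list(upto = 132, range = c(59, 87)),
    list(upto = 180, range = c(59, 89)), list(upto = Inf, range = c(60, 91))
  ), am)
  hr_min <- .age_bracket(list(
    list(upto = 6, range = c(110, 130)), list(upto = 12, range = c(90, 130)),
    list(upto = 36, range = c(80, 110)), list(upto = 72, range = c(75, 110)),
    list(upto = 132, range = c(65, 110)), list(upto = Inf, range = c(60, 90))
  ), am)
  hr_max <- .age_bracket(list(
    list(upto = 6, range = c(150, 180)), list(upto = 12, range = c(145, 180)),
    list(upto = 36, range = c(140, 180)), list(upto = 72, range = c(130, 160)),
    list(upto = 108, range = c(125, 160)), list(upto = 132, range = c(120, 160)),
    list(upto = 180, range = c(115, 160)), list(upto = Inf, range = c(110, 150))
  ), am)

  v_b <- if (am <= 3) 100 else 75  # blood volume per kg, ml/kg
  d_v <- c(0.1 * v_b / C_MAX_PER_KG, 0.3 * v_b / C_MIN_PER_KG)
  i_cap <- 0.25 * v_b / (3600 * C_MIN_PER_KG)

  b <- rbind(
    p_set = p_set,
    c_v_rel = c(10, 40),
    d_v_v0_rel = d_v,
    i_ex_rel = c(-i_cap, i_cap),
    hr_min = hr_min,
    hr_max = hr_max,
    r_min_scaled = c(0.1, 2.5),
    r_max_scaled = c(0.25, 3),
    k_min_rel = c(2 / C_MAX_PER_KG, 30 / C_MIN_PER_KG),
    k_max_rel = c(50 / C_MAX_PER_KG, 200 / C_MIN_PER_KG),
    s_const = c(0, 1),
    s_slope = c(-1 / 300, 1 / 300),
    m_const = c(-1, 1),
    m_slope = c(-1 / 150, 1 / 150),
    alpha_rc = c(0.1, 10)
  )
  out <- data.frame(lo = b[, 1], hi = b[, 2], row.names = PARAM_NAMES)
  class(out) <- c("param_bounds", "data.frame")
  out
}

#' Tighten parameter bounds from observed data
#'
#' The extremes already seen in a patient's record constrain the rate
#' parameters: the minimal heart rate cannot exceed the smallest observed
#' heart rate, the maximal heart rate cannot be below the largest observed
#' one, and analogously for the scaled resistance range via the RC channel.
#' Bounds only ever tighten; a tightening that would empty an interval is
#' widened to a one-unit interval around the observed extremum, with a
#' warning.
#'
#' @param bounds A `param_bounds` from [build_bounds()].
#' @param obs An `observable_series` (or any data frame with `hr` and `rc`)
#'   holding the measurements seen so far.
#' @return Updated `param_bounds`.
#' @export
update_bounds_from_observables <- function(bounds, obs) {
  stopifnot(inherits(bounds, "param_bounds"))
  tighten <- function(b, param, side, value) {
    lo <- b[param, "lo"]; hi <- b[param, "hi"]
    if (side == "hi") hi <- min(hi, value) else lo <- max(lo, value)
    if (lo >= hi) {
      warning("observed extremum empties the `", param,
              "` interval; widening to a unit interval")
      lo <- value - 0.5; hi <- value + 0.5
    }
    b[param, c("lo", "hi")] <- c(lo, hi)
    b
  }
  bounds <- tighten(bounds, "hr_min", "hi", min(obs$hr))
  bounds <- tighten(bounds, "hr_max", "lo", max(obs$hr))
  bounds <- tighten(bounds, "r_min_scaled", "hi", min(obs$rc))
  bounds <- tighten(bounds, "r_max_scaled", "lo", max(obs$rc))
  bounds
}

#' Cost-function configuration
#'
#' Weights, history-penalty constants and windowing defaults of the
#' segment objective. Residual weights emphasize the derivative-bearing
#' volume and flow terms; normalizers are recomputed per segment from the
#' data (means of the observed channels, and the upper bound of the scaled
#' volume rate for the volume term).
#'
#' @param w_h,w_r,w_p,w_i,w_a Term weights (heart rate, resistance, pulse
#'   pressure, volume bookkeeping, arterial flow).
#' @param beta History-penalty weight.
#' @param tau History memory constant, s.
#' @param segment_length Segment length `T`, s.
#' @param stride Segment stride, s.
#' @param n_starts Random restarts per segment.
#' @param deriv_window,deriv_order Savitzky-Golay smoothing-derivative
#'   window (s) and polynomial order for the pressure-derivative channels.
#' @param smooth_segments Centered moving-average span (in segments) for the
#'   smoothed parameter trajectory.
#' @param maxit Iteration cap per local minimization.
#' @return List of class `cost_config`.
#' @export
cost_config <- function(w_h = 1, w_r = 0.2, w_p = 0.2, w_i = 0.2, w_a = 10,
                        beta = 0.1, tau = 500,
                        segment_length = 300, stride = 100, n_starts = 5,
                        deriv_window = 30, deriv_order = 2,
                        smooth_segments = 5, maxit = 500) {
  cfg <- list(w_h = w_h, w_r = w_r, w_p = w_p, w_i = w_i, w_a = w_a,
              beta = beta, tau = tau, segment_length = segment_length,
              stride = stride, n_starts = n_starts,
              deriv_window = deriv_window, deriv_order = deriv_order,
              smooth_segments = smooth_segments, maxit = maxit)
  if (any(unlist(cfg[1:5]) < 0)) stop("weights must be nonnegative", call. = FALSE)
  structure(cfg, class = "cost_config")
}

#' Split an observable series into overlapping analysis windows
#'
#' Windows of length `T` starting every `stride` seconds. A window whose
#' end would coincide exactly with the record end is dropped (a 25-minute
#' record yields 12 windows), except that a record exactly one window long
#' yields that single window. Each window carries the validity screen of
#' [validate_segment()].
#'
#' @param obs An `observable_series`.
#' @param segment_length Window length `T`, s.
#' @param stride Window stride, s.
#' @return Data frame with columns `start`, `end`, `valid`, `reason`.
#' @export
segment_series <- function(obs, segment_length = 300, stride = 100) {
  stopifnot(inherits(obs, "observable_series"))
  fs <- attr(obs, "fs")
  len <- max(obs$t) - min(obs$t) + 1 / fs
  tol <- 1 / (2 * fs)  # half a sample: guards float dirt at window ends
  if (len < segment_length - tol) {
    warning("record shorter than one segment; nothing to analyze")
    return(data.frame(start = numeric(0), end = numeric(0),
                      valid = logical(0), reason = character(0)))
  }
  starts <- seq(0, len, by = stride)
  ## drop a window whose end reaches (or passes) the record end ...
  starts <- starts[starts + segment_length < len - tol]
  ## ... except that a record exactly one window long yields that window
  if (!length(starts)) starts <- 0
  t0 <- min(obs$t)
  out <- data.frame(start = starts, end = starts + segment_length,
                    valid = NA, reason = NA_character_)
  for (i in seq_len(nrow(out))) {
    idx <- obs$t - t0 >= out$start[i] & obs$t - t0 < out$end[i]
    v <- validate_segment(obs[idx, ])
    out$valid[i] <- v$valid
    out$reason[i] <- v$reason
  }
  out
}

## Smoothed first-derivative channels for the whole series
## (Savitzky-Golay, window in seconds, output in units/s).
.derivative_channel <- function(x, fs, window_s, order) {
  n <- round(window_s * fs)
  if (n %% 2 == 0) n <- n + 1
  n <- min(n, if (length(x) %% 2 == 0) length(x) - 1 else length(x))
  if (n < order + 2) n <- order + 2 + (order %% 2)
  as.numeric(signal::sgolayfilt(x, p = order, n = n, m = 1, ts = 1 / fs))
}

## Precompute everything the objective needs for one segment.
.segment_data <- function(obs, start, segment_length, config,
                          bounds) {
  fs <- attr(obs, "fs")
  t0 <- min(obs$t)
  dpa_full <- .derivative_channel(obs$p_a, fs, config$deriv_window,
                                  config$deriv_order)
  dpv_full <- .derivative_channel(obs$p_v, fs, config$deriv_window,
                                  config$deriv_order)
  idx <- which(obs$t - t0 >= start & obs$t - t0 < start + segment_length)
  seg <- obs[idx, ]
  if (any(seg$p_a <= seg$p_v))
    stop("segment has P_a <= P_v: pressure ordering violated", call. = FALSE)
  list(
    start = start,
    t_rel = seg$t - t0 - start,
    pa = seg$p_a, pv = seg$p_v,
    hr = seg$hr, hr_bps = seg$hr / 60,
    pp = seg$p_p, rc = seg$rc,
    dpa = dpa_full[idx], dpv = dpv_full[idx],
    dt = 1 / fs,
    norm = list(h = mean(seg$hr), r = mean(seg$rc), p = mean(seg$p_p),
                a = mean(seg$hr / 60 * seg$p_p),
                i = bounds["i_ex_rel", "hi"])
  )
}

#' Residual terms of the model cost at one parameter point
#'
#' Evaluates the five residual channels linking the observables of a
#' segment to a candidate parameter set: heart rate, scaled resistance,
#' pulse pressure, volume bookkeeping (with derivative channels), and the
#' arterial flow balance (heart rate in beats/s there). The baroreflex is
#' computed from the measured arterial pressure; the independent drive and
#' the resistance modulation are linear in segment time, clipped to their
#' admissible ranges.
#'
#' @param seg Segment data from an `observable_series` restricted to one
#'   window (rows with `t`, `p_a`, `p_v`, `hr`, `p_p`, `rc`), or an
#'   internal segment-data list.
#' @param theta A [scaled_params()] object or named numeric vector of the
#'   fifteen parameters.
#' @param config A [cost_config()] (used for the derivative channels when
#'   `seg` is a raw data frame).
#' @return Data frame with columns `f_h`, `f_r`, `f_p`, `f_i`, `f_a` (one
#'   row per 10 Hz sample).
#' @export
cost_terms <- function(seg, theta, config = cost_config()) {
  if (!is.list(seg) || is.data.frame(seg)) {
    obs <- as_observable_series(seg, fs = round(1 / stats::median(diff(seg$t))))
    dummy_bounds <- data.frame(lo = 0, hi = 1,
                               row.names = "i_ex_rel")
    class(dummy_bounds) <- c("param_bounds", "data.frame")
    seg <- .segment_data(obs, 0, max(obs$t) - min(obs$t) + 1e-9, config,
                         dummy_bounds)
  }
  th <- if (inherits(theta, "scaled_params")) theta else as.list(theta)
  r <- .residuals(seg, th)
  data.frame(f_h = r$f_h, f_r = r$f_r, f_p = r$f_p, f_i = r$f_i,
             f_a = r$f_a)
}

## Core residual computation (vectorized over the segment grid).
.residuals <- function(seg, th) {
  kb <- if (!is.null(th$k_b)) th$k_b else KB_DEFAULT
  s_b <- 1 - stats::plogis(kb * (seg$pa - th$p_set))
  s_lin <- th$s_const + th$s_slope * seg$t_rel
  s <- pmin(1, pmax(0, s_lin))
  m <- pmin(1, pmax(-1, th$m_const + th$m_slope * seg$t_rel))
  s_tot <- stats::plogis(SIGMOID_GAIN * (s_b + s - 1))
  r_mod <- stats::plogis(SIGMOID_GAIN * (s_tot + m))
  r_model <- th$r_min_scaled + (th$r_max_scaled - th$r_min_scaled) * r_mod

  f_h <- th$hr_min + (th$hr_max - th$hr_min) * s_tot - seg$hr
  f_r <- r_model - seg$rc
  k_rel <- th$k_min_rel + (th$k_max_rel - th$k_min_rel) * s_tot
  f_p <- k_rel * seg$pv / (seg$pa - seg$pv) - seg$pp

  ds_b <- -kb * s_b * (1 - s_b) * seg$dpa
  ds <- th$s_slope * (s_lin > 0 & s_lin < 1)
  ds_tot <- SIGMOID_GAIN * s_tot * (1 - s_tot) * (ds_b + ds)
  f_i <- seg$dpa + th$c_v_rel * seg$dpv - th$d_v_v0_rel * ds_tot -
    th$i_ex_rel
  f_a <- seg$hr_bps * seg$pp - (seg$pa - seg$pv) * th$alpha_rc / r_model -
    seg$dpa

  list(f_h = f_h, f_r = f_r, f_p = f_p, f_i = f_i, f_a = f_a,
       s_tot = s_tot, r_mod = r_mod, s = s, m = m)
}

## Analytic gradient of J with respect to the 15 parameters (in canonical
## order). Mirrors .residuals(): every residual is differentiated through
## the sigmoid chain; clipped drive samples contribute zero slope.
.objective_gradient <- function(seg, th, config, history, bounds) {
  kb <- if (!is.null(th$k_b)) th$k_b else KB_DEFAULT
  g <- SIGMOID_GAIN
  t <- seg$t_rel
  s_b <- 1 - stats::plogis(kb * (seg$pa - th$p_set))
  s_lin <- th$s_const + th$s_slope * t
  ind_s <- as.numeric(s_lin > 0 & s_lin < 1)
  s <- pmin(1, pmax(0, s_lin))
  m_lin <- th$m_const + th$m_slope * t
  ind_m <- as.numeric(m_lin > -1 & m_lin < 1)
  m <- pmin(1, pmax(-1, m_lin))
  st <- stats::plogis(g * (s_b + s - 1))
  rm <- stats::plogis(g * (st + m))
  r_span <- th$r_max_scaled - th$r_min_scaled
  r_model <- th$r_min_scaled + r_span * rm

  ## d st / d {p_set, s_const, s_slope}
  dst_dd <- g * st * (1 - st)
  dsb_dpset <- kb * s_b * (1 - s_b)
  dst <- list(p_set = dst_dd * dsb_dpset,
              s_const = dst_dd * ind_s,
              s_slope = dst_dd * ind_s * t)
  ## d rm / d {p_set, s_const, s_slope, m_const, m_slope}
  drm_dd <- g * rm * (1 - rm)
  drm <- list(p_set = drm_dd * dst$p_set,
              s_const = drm_dd * dst$s_const,
              s_slope = drm_dd * dst$s_slope,
              m_const = drm_dd * ind_m,
              m_slope = drm_dd * ind_m * t)

  f_h <- th$hr_min + (th$hr_max - th$hr_min) * st - seg$hr
  f_r <- r_model - seg$rc
  q <- seg$pv / (seg$pa - seg$pv)
  k_span <- th$k_max_rel - th$k_min_rel
  f_p <- (th$k_min_rel + k_span * st) * q - seg$pp

  ds_b <- -kb * s_b * (1 - s_b) * seg$dpa
  ds_drive <- ds_b + th$s_slope * ind_s
  ds_tot <- g * st * (1 - st) * ds_drive
  f_i <- seg$dpa + th$c_v_rel * seg$dpv - th$d_v_v0_rel * ds_tot -
    th$i_ex_rel
  grad_flow <- (seg$pa - seg$pv) * th$alpha_rc / r_model
  f_a <- seg$hr_bps * seg$pp - grad_flow - seg$dpa

  ## d ds_tot / d {p_set, s_const, s_slope}
  dds_b_dpset <- -kb * (1 - 2 * s_b) * dsb_dpset * seg$dpa
  dds_tot <- list(
    p_set = g * (1 - 2 * st) * dst$p_set * ds_drive +
      g * st * (1 - st) * dds_b_dpset,
    s_const = g * (1 - 2 * st) * dst$s_const * ds_drive,
    s_slope = g * (1 - 2 * st) * dst$s_slope * ds_drive +
      g * st * (1 - st) * ind_s)

  hr_span <- th$hr_max - th$hr_min
  zero <- numeric(length(t))
  d_f <- function(param) {
    dstx <- dst[[param]]; if (is.null(dstx)) dstx <- zero
    drmx <- drm[[param]]; if (is.null(drmx)) drmx <- zero
    ddstx <- dds_tot[[param]]; if (is.null(ddstx)) ddstx <- zero
    dr_model <- switch(param,
      r_min_scaled = 1 - rm, r_max_scaled = rm, r_span * drmx)
    list(
      h = switch(param, hr_min = 1 - st, hr_max = st, hr_span * dstx),
      r = dr_model,
      p = switch(param, k_min_rel = (1 - st) * q, k_max_rel = st * q,
                 k_span * q * dstx),
      i = switch(param, c_v_rel = seg$dpv, d_v_v0_rel = -ds_tot,
                 i_ex_rel = rep(-1, length(t)),
                 -th$d_v_v0_rel * ddstx),
      a = switch(param, alpha_rc = -(seg$pa - seg$pv) / r_model,
                 grad_flow / r_model * dr_model)
    )
  }

  nm <- seg$norm
  grad <- vapply(PARAM_NAMES, function(param) {
    d <- d_f(param)
    2 * seg$dt * sum(
      config$w_h * f_h * d$h / nm$h + config$w_r * f_r * d$r / nm$r +
      config$w_p * f_p * d$p / nm$p + config$w_i * f_i * d$i / nm$i +
      config$w_a * f_a * d$a / nm$a)
  }, numeric(1))

  if (config$beta > 0 && !is.null(history) && nrow(history) > 0) {
    mem <- c("c_v_rel", "d_v_v0_rel", "p_set", "hr_max", "hr_min",
             "r_max_scaled", "r_min_scaled")
    wts <- exp(-(seg$start - history$start) / config$tau)
    for (p in mem) {
      b_i <- bounds[p, "hi"]
      grad[p] <- grad[p] - 2 * config$beta / b_i^2 *
        sum(wts * (history[[p]] - th[[p]]))
    }
  }
  grad
}

## J(theta) for a prepared segment, including the history penalty.
.objective_value <- function(seg, th, config, history, bounds) {
  r <- .residuals(seg, th)
  nm <- seg$norm
  integrand <- config$w_h * r$f_h^2 / nm$h + config$w_r * r$f_r^2 / nm$r +
    config$w_p * r$f_p^2 / nm$p + config$w_i * r$f_i^2 / nm$i +
    config$w_a * r$f_a^2 / nm$a
  j <- sum(integrand) * seg$dt  # left-Riemann sum on the observable grid

  if (config$beta > 0 && !is.null(history) && nrow(history) > 0) {
    mem <- c("c_v_rel", "d_v_v0_rel", "p_set", "hr_max", "hr_min",
             "r_max_scaled", "r_min_scaled")
    wts <- exp(-(seg$start - history$start) / config$tau)
    for (p in mem) {
      b_i <- bounds[p, "hi"]
      j <- j + config$beta / b_i^2 *
        sum(wts * (history[[p]] - th[[p]])^2)
    }
  }
  j
}

#' Segment objective function
#'
#' The quantity minimized per segment: the time integral (left-Riemann sum
#' on the observable grid) of the weighted, normalized squared residuals,
#' plus a recency-weighted quadratic penalty tying the slowly-varying
#' parameters (compliance ratio, unstressed-volume reserve, set point, and
#' the heart-rate and resistance range ends) to their estimates in earlier
#' segments.
#'
#' @param seg Segment rows of an `observable_series`, or an internal
#'   segment-data list.
#' @param theta [scaled_params()] or named numeric vector.
#' @param config A [cost_config()].
#' @param history Data frame of earlier segment estimates (columns `start`
#'   plus parameter names); `NULL` or empty disables the penalty.
#' @param bounds A `param_bounds` (supplies the volume-rate normalizer and
#'   the penalty scales). Defaults to neonatal bounds.
#' @return Scalar objective value.
#' @export
segment_objective <- function(seg, theta, config = cost_config(),
                              history = NULL,
                              bounds = build_bounds(patient_meta(0.02, 3.5))) {
  if (!is.list(seg) || is.data.frame(seg)) {
    obs <- as_observable_series(seg, fs = round(1 / stats::median(diff(seg$t))))
    seg <- .segment_data(obs, 0, max(obs$t) - min(obs$t) + 1e-9, config,
                         bounds)
  }
  th <- if (inherits(theta, "scaled_params")) theta else as.list(theta)
  .objective_value(seg, th, config, history, bounds)
}

.theta_vec_to_list <- function(x) {
  th <- as.list(x)
  names(th) <- PARAM_NAMES
  th
}

## Deterministic warm start inverted from the observables: assumes a
## mid-range autonomic configuration, reads the activation profile off the
## heart-rate channel, and solves the remaining ranges by linear least
## squares. Used as the first restart of every segment estimation.
.warm_start <- function(seg, bounds) {
  clamp <- function(x, l, h) pmin(h, pmax(l, x))
  lo <- bounds$lo; hi <- bounds$hi
  th <- stats::setNames((lo + hi) / 2, PARAM_NAMES)
  kb <- KB_DEFAULT

  st_obs <- clamp((seg$hr - th["hr_min"]) / (th["hr_max"] - th["hr_min"]),
                  0.02, 0.98)
  s0 <- 0.5
  sb_need <- clamp(1 - s0 + stats::qlogis(st_obs) / SIGMOID_GAIN, 0.02, 0.98)
  th["p_set"] <- clamp(stats::median(seg$pa - stats::qlogis(1 - sb_need) / kb),
                       bounds["p_set", "lo"], bounds["p_set", "hi"])
  th["s_const"] <- s0; th["s_slope"] <- 0
  th["m_const"] <- 0; th["m_slope"] <- 0

  rm <- stats::plogis(SIGMOID_GAIN * st_obs)
  fr <- stats::lm.fit(cbind(1, rm), seg$rc)$coefficients
  th["r_min_scaled"] <- clamp(fr[1], bounds["r_min_scaled", "lo"],
                              bounds["r_min_scaled", "hi"])
  th["r_max_scaled"] <- clamp(fr[1] + max(fr[2], 0.05),
                              max(bounds["r_max_scaled", "lo"],
                                  th["r_min_scaled"] + 0.01),
                              bounds["r_max_scaled", "hi"])

  q <- seg$pv / (seg$pa - seg$pv)
  fk <- stats::lm.fit(cbind(1, st_obs), seg$pp / q)$coefficients
  th["k_min_rel"] <- clamp(fk[1], bounds["k_min_rel", "lo"],
                           bounds["k_min_rel", "hi"])
  th["k_max_rel"] <- clamp(fk[1] + max(fk[2], 10),
                           max(bounds["k_max_rel", "lo"],
                               th["k_min_rel"] + 1),
                           bounds["k_max_rel", "hi"])

  th["alpha_rc"] <- clamp(
    mean((seg$hr_bps * seg$pp - seg$dpa) * seg$rc / (seg$pa - seg$pv)),
    bounds["alpha_rc", "lo"], bounds["alpha_rc", "hi"])

  s_b <- 1 - stats::plogis(kb * (seg$pa - th["p_set"]))
  st <- stats::plogis(SIGMOID_GAIN * (s_b + s0 - 1))
  ds_tot <- SIGMOID_GAIN * st * (1 - st) * (-kb * s_b * (1 - s_b) * seg$dpa)
  th["i_ex_rel"] <- clamp(
    mean(seg$dpa + th["c_v_rel"] * seg$dpv - th["d_v_v0_rel"] * ds_tot),
    bounds["i_ex_rel", "lo"], bounds["i_ex_rel", "hi"])
  th
}

#' Estimate the hidden parameters of one segment
#'
#' Constrained multi-start minimization of the segment objective: from
#' `n_starts` seeded uniform-random points inside the (possibly tightened)
#' bounds, runs box-constrained quasi-Newton local searches in normalized
#' coordinates and keeps the lowest-objective solution. Reproducible given
#' the seed.
#'
#' @param seg Segment rows of an `observable_series`, or an internal
#'   segment-data list.
#' @param bounds A `param_bounds`.
#' @param config A [cost_config()].
#' @param history Earlier segment estimates (see [segment_objective()]).
#' @param n_starts Number of random restarts (default from `config`).
#' @param seed Integer seed.
#' @return List of class `segment_estimate` with elements `theta` (named
#'   vector), `cost`, `winner` (restart index), `start` (segment start, s)
#'   and `restarts` (per-restart objective values).
#' @export
estimate_segment <- function(seg, bounds, config = cost_config(),
                             history = NULL, n_starts = config$n_starts,
                             seed = 1L) {
  if (n_starts < 1) stop("`n_starts` must be at least 1", call. = FALSE)
  if (!is.list(seg) || is.data.frame(seg)) {
    obs <- as_observable_series(seg, fs = round(1 / stats::median(diff(seg$t))))
    seg <- .segment_data(obs, 0, max(obs$t) - min(obs$t) + 1e-9, config,
                         bounds)
  }
  lo <- bounds$lo; hi <- bounds$hi
  span <- hi - lo

  obj_x <- function(x) {
    th <- .theta_vec_to_list(lo + x * span)
    .objective_value(seg, th, config, history, bounds)
  }
  grad_x <- function(x) {
    th <- .theta_vec_to_list(lo + x * span)
    .objective_gradient(seg, th, config, history, bounds) * span
  }

  rng <- .seeded_rng(seed)
  best <- NULL
  restarts <- numeric(n_starts)
  for (r in seq_len(n_starts)) {
    ## first restart: deterministic observable-inverted warm start;
    ## the rest: seeded uniform draws inside the bounds
    x0 <- if (r == 1) (.warm_start(seg, bounds) - lo) / span
          else rng$runif(length(lo))
    fit <- tryCatch(
      stats::optim(x0, obj_x, grad_x, method = "L-BFGS-B",
                   lower = 0, upper = 1,
                   control = list(maxit = config$maxit, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) { restarts[r] <- NA_real_; next }
    restarts[r] <- fit$value
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$winner <- r
    }
  }
  if (is.null(best))
    stop("all restarts failed to converge", call. = FALSE)
  theta <- lo + best$par * span
  names(theta) <- PARAM_NAMES
  structure(list(theta = theta, cost = best$value, winner = best$winner,
                 start = seg$start, restarts = restarts),
            class = "segment_estimate")
}

#' @export
print.segment_estimate <- function(x, ...) {
  cat(sprintf("segment estimate @ %.0f s: J = %.4g (restart %d of %d)\n",
              x$start, x$cost, x$winner, length(x$restarts)))
  invisible(x)
}

#' Estimate the parameter trajectory of a whole record
#'
#' Runs the full per-segment estimation over a record: splits the series
#' into overlapping windows, tightens the rate bounds from the data seen up
#' to each window, estimates every valid window with the history penalty
#' carried forward, and smooths each parameter series with a centered
#' moving average.
#'
#' @param obs An `observable_series`.
#' @param meta A [patient_meta()] (drives the bounds).
#' @param config A [cost_config()].
#' @param seed Master integer seed; per-segment streams are derived
#'   deterministically.
#' @param bounds Optional pre-built bounds (default from `meta`).
#' @return Object of class `estimate_trace`: list with `segments` (data
#'   frame: `start`, `valid`, the 15 parameters, `cost`, `winner`),
#'   `smoothed` (same parameter columns, moving-averaged), `windows` (the
#'   segmentation table), `bounds` (final tightened bounds) and `config`.
#' @export
estimate_trace <- function(obs, meta, config = cost_config(), seed = 1L,
                           bounds = NULL) {
  stopifnot(inherits(obs, "observable_series"))
  if (is.null(bounds)) bounds <- build_bounds(meta)
  windows <- segment_series(obs, config$segment_length, config$stride)
  valid_idx <- which(windows$valid)
  if (!length(valid_idx)) {
    warning("no valid segments; empty estimate")
    return(structure(list(segments = NULL, smoothed = NULL,
                          windows = windows, bounds = bounds,
                          config = config),
                     class = "estimate_trace"))
  }

  t0 <- min(obs$t)
  history <- NULL
  rows <- list()
  for (i in valid_idx) {
    w_end <- windows$end[i]
    seen <- obs[obs$t - t0 < w_end, ]
    bounds <- update_bounds_from_observables(bounds, seen)
    seg <- .segment_data(obs, windows$start[i], config$segment_length,
                         config, bounds)
    est <- estimate_segment(seg, bounds, config, history,
                            seed = (seed * 373L + i * 7919L) %% .Machine$integer.max)
    row <- as.data.frame(as.list(est$theta))
    row$start <- est$start
    row$cost <- est$cost
    row$winner <- est$winner
    rows[[length(rows) + 1L]] <- row
    history <- rbind(history, row[c("start", PARAM_NAMES)])
  }
  segments <- do.call(rbind, rows)
  segments <- segments[c("start", PARAM_NAMES, "cost", "winner")]

  smoothed <- segments
  for (p in PARAM_NAMES)
    smoothed[[p]] <- .moving_average(segments[[p]], config$smooth_segments)

  structure(list(segments = segments, smoothed = smoothed,
                 windows = windows, bounds = bounds, config = config),
            class = "estimate_trace")
}

#' @export
print.estimate_trace <- function(x, ...) {
  nw <- nrow(x$windows); nv <- if (is.null(x$segments)) 0 else nrow(x$segments)
  cat(sprintf("estimate trace: %d/%d windows estimated\n", nv, nw))
  if (nv) {
    ix <- shock_indices(x)
    cat(sprintf("  mean I_bar_ex %.4f 1/min | mean M_SVR %.3f | mean K~max %.0f mmHg\n",
                ix$summary$i_bar_ex[1], ix$summary$m_svr[1],
                ix$summary$k_max_rel[1]))
  }
  invisible(x)
}

#' Shock indices from an estimate trace
#'
#' Derives the three clinical markers per segment: the relative
#' intravascular volume change `I_bar_ex = I_ex_rel / dV_v0_rel` (converted
#' to 1/min; negative while bleeding, weight-independent), the non-autonomic
#' resistance modulation `M_SVR` evaluated at the segment midpoint (negative
#' in distributive states) and the maximal relative contractility
#' `K_max_rel` (depressed in cardiogenic states), plus their window means
#' and standard errors.
#'
#' @param est An `estimate_trace` (or its `segments` data frame).
#' @return List with `per_segment` (data frame: `start`, `i_bar_ex`,
#'   `m_svr`, `k_max_rel`) and `summary` (one row of means and standard
#'   errors).
#' @export
shock_indices <- function(est) {
  seg <- if (inherits(est, "estimate_trace")) est$segments else est
  if (is.null(seg) || !nrow(seg)) stop("empty estimate trace", call. = FALSE)
  t_mid <- if (inherits(est, "estimate_trace"))
    est$config$segment_length / 2 else 150
  per <- data.frame(
    start = seg$start,
    i_bar_ex = 60 * seg$i_ex_rel / seg$d_v_v0_rel,
    m_svr = pmin(1, pmax(-1, seg$m_const + seg$m_slope * t_mid)),
    k_max_rel = seg$k_max_rel
  )
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  summary <- data.frame(
    i_bar_ex = mean(per$i_bar_ex), i_bar_ex_se = se(per$i_bar_ex),
    m_svr = mean(per$m_svr), m_svr_se = se(per$m_svr),
    k_max_rel = mean(per$k_max_rel), k_max_rel_se = se(per$k_max_rel)
  )
  list(per_segment = per, summary = summary)
}

#' Reconstruct the fast observables from estimated parameters
#'
#' Feeds an estimated parameter set back through the model relations to
#' reconstruct heart rate, scaled resistance and pulse pressure from the
#' measured pressures, and correlates each reconstruction with its observed
#' channel. Fast fluctuations are not reproduced by construction, since the
#' drives are linear within a segment. A constant observed channel has an
#' undefined correlation, reported as `NA` with `constant_channel = TRUE`.
#'
#' @param theta [scaled_params()] or named numeric vector.
#' @param seg Segment rows of an `observable_series`.
#' @return List with `reconstruction` (data frame: `t`, `hr_bar`, `rc_bar`,
#'   `p_p_bar`), `correlations` (named vector over `hr`, `rc`, `p_p`) and
#'   `constant_channel` (named logical).
#' @export
reconstruct_observables <- function(theta, seg) {
  th <- if (inherits(theta, "scaled_params")) theta else as.list(theta)
  t_rel <- seg$t - min(seg$t)
  sd0 <- list(t_rel = t_rel, pa = seg$p_a, pv = seg$p_v,
              hr = seg$hr, hr_bps = seg$hr / 60, pp = seg$p_p, rc = seg$rc,
              dpa = 0, dpv = 0, dt = 1, start = 0,
              norm = list(h = 1, r = 1, p = 1, a = 1, i = 1))
  r <- .residuals(sd0, th)
  rec <- data.frame(
    t = seg$t,
    hr_bar = th$hr_min + (th$hr_max - th$hr_min) * r$s_tot,
    rc_bar = th$r_min_scaled + (th$r_max_scaled - th$r_min_scaled) * r$r_mod,
    p_p_bar = (th$k_min_rel + (th$k_max_rel - th$k_min_rel) * r$s_tot) *
      seg$p_v / (seg$p_a - seg$p_v)
  )
  obs_ch <- list(hr = seg$hr, rc = seg$rc, p_p = seg$p_p)
  rec_ch <- list(hr = rec$hr_bar, rc = rec$rc_bar, p_p = rec$p_p_bar)
  const <- vapply(obs_ch, function(x) stats::sd(x) < 1e-12, logical(1))
  cors <- vapply(names(obs_ch), function(nm) {
    if (const[[nm]] || stats::sd(rec_ch[[nm]]) < 1e-12) NA_real_
    else stats::cor(obs_ch[[nm]], rec_ch[[nm]])
  }, numeric(1))
  list(reconstruction = rec, correlations = cors,
       constant_channel = const)
}
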