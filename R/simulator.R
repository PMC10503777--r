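#' Piecewise-linear drive schedule
#'
#' Scenario drives (volume change rate, autonomic drive, resistance
#' modulation) are piecewise-linear functions of time given by knot times and
#' values; evaluation holds the end values constant outside the knot range.
#'
#' @param times Knot times, s (strictly increasing).
#' @param values Values at the knots.
#' @return Object of class `schedule`.
#' @export
#' @examples
#' ramp <- schedule(c(0, 300, 1200), c(0, 0, -0.06))  # bleeding onset at 5 min
#' eval_schedule(ramp, c(0, 750, 1500))
schedule <- function(times, values) {
  if (length(times) != length(values) || length(times) < 1)
    stop("`times` and `values` must be equal-length, nonempty", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1)
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values))) stop("schedule values must be finite", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "schedule")
}

#' @rdname schedule
#' @param x A `schedule`.
#' @param t Times at which to evaluate, s.
#' @export
eval_schedule <- function(x, t) {
  stopifnot(inherits(x, "schedule"))
  if (length(x$times) == 1) return(rep(x$values, length(t)))
  stats::approx(x$times, x$values, xout = t, rule = 2)$y
}

#' @rdname schedule
#' @export
schedule_slope <- function(x, t) {
  stopifnot(inherits(x, "schedule"))
  n <- length(x$times)
  if (n == 1) return(rep(0, length(t)))
  slopes <- diff(x$values) / diff(x$times)
  idx <- findInterval(t, x$times, rightmost.closed = TRUE)
  out <- ifelse(idx >= 1 & idx < n, slopes[pmax(idx, 1)], 0)
  out[t < x$times[1] | t >= x$times[n]] <- 0
  out
}

#' Shock scenario definition
#'
#' A scenario bundles the time-dependent external inputs of a simulation:
#' the intravascular volume change rate `i_ex` (ml/s), the independent
#' autonomic drive `s` (clipped to \[0, 1\]) and the non-autonomic resistance
#' modulation `m_svr` (clipped to \[-1, 1\]), each a piecewise-linear
#' [schedule()].
#'
#' @param name Label.
#' @param duration Scenario length, s.
#' @param i_ex,s,m_svr Drive schedules (constants are promoted).
#' @return Object of class `cvs_scenario`.
#' @export
cvs_scenario <- function(name, duration = 1500,
                         i_ex = 0, s = 0.2, m_svr = 0) {
  as_sched <- function(x) if (inherits(x, "schedule")) x else schedule(0, x)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  structure(list(name = name, duration = duration,
                 i_ex = as_sched(i_ex), s = as_sched(s),
                 m_svr = as_sched(m_svr)),
            class = "cvs_scenario")
}

#' @export
print.cvs_scenario <- function(x, ...) {
  cat(sprintf("scenario '%s' (%.0f s)\n", x$name, x$duration))
  invisible(x)
}

#' Library of reference shock scenarios
#'
#' Named scenarios mirroring the simulated artificial patients: `control`
#' (all drives constant), `hypovolemic` (volume withdrawal ramping in over
#' 15 minutes), `distributive` (non-autonomic vasodilation ramping down over
#' 15 minutes), `combined` (both), and `fight_or_flight` (a rise in the
#' independent autonomic drive). Ramp magnitudes are chosen so the resulting
#' observables stay inside the validity ranges of the segment screen.
#'
#' @param name Scenario name; omit to list available names.
#' @param duration Scenario length, s (default 1500, a 25-minute window).
#' @param i_ex_min Terminal volume withdrawal rate for hypovolemic ramps,
#'   ml/s (negative).
#' @param m_svr_min Terminal non-autonomic modulation for distributive
#'   ramps.
#' @param s_base Baseline independent autonomic drive.
#' @return A [cvs_scenario()] (or character vector of names).
#' @export
scenario_library <- function(name = NULL, duration = 1500,
                             i_ex_min = -0.06, m_svr_min = -0.5,
                             s_base = 0.2) {
  t0 <- min(300, duration / 5)
  t1 <- min(t0 + 900, duration)
  ramp <- function(lo) schedule(c(0, t0, t1), c(0, 0, lo))
  builders <- list(
    control = function() cvs_scenario("control", duration, s = s_base),
    hypovolemic = function()
      cvs_scenario("hypovolemic", duration, i_ex = ramp(i_ex_min), s = s_base),
    distributive = function()
      cvs_scenario("distributive", duration, m_svr = ramp(m_svr_min),
                   s = s_base),
    combined = function()
      cvs_scenario("combined", duration, i_ex = ramp(i_ex_min),
                   m_svr = ramp(m_svr_min), s = s_base),
    fight_or_flight = function()
      cvs_scenario("fight_or_flight", duration,
                   s = schedule(c(0, t0, t0 + 300), c(s_base, s_base, 1)))
  )
  if (is.null(name)) return(names(builders))
  b <- builders[[name]]
  if (is.null(b)) stop("unknown scenario '", name, "'; available: ",
                       paste(names(builders), collapse = ", "), call. = FALSE)
  b()
}

.drives_at <- function(scenario, t) {
  list(
    i_ex = eval_schedule(scenario$i_ex, t),
    s = pmin(1, pmax(0, eval_schedule(scenario$s, t))),
    m_svr = pmin(1, pmax(-1, eval_schedule(scenario$m_svr, t))),
    s_slope = schedule_slope(scenario$s, t)
  )
}

#' Simulate the cardiovascular model
#'
#' Integrates the two pressure ODEs with a fixed-step fourth-order
#' Runge-Kutta scheme under a scenario's drive schedules, recording the full
#' hidden state (baroreflex, total activation, resistance, pulse pressure)
#' alongside the pressures. Divergence beyond 500 mmHg or collapse of the
#' arterial-venous gradient aborts with the failure time.
#'
#' @param params [physical_params()] object.
#' @param scenario [cvs_scenario()] object (or a name understood by
#'   [scenario_library()]).
#' @param dt Integration step, s.
#' @param initial Named vector or list with starting `p_a`, `p_v` (mmHg);
#'   default 48 and 4 mmHg.
#' @param alpha_rc Scale applied to the emitted resistance-compliance
#'   product (the pulse-contour scale of a matching waveform record).
#' @return A `cvs_trace`: data frame with columns `t, p_a, p_v, hr, p_p, rc,
#'   s_b, s_tot, i_ex, m_svr, s`, with the parameter set and scenario kept
#'   as attributes.
#' @export
simulate_cvs <- function(params, scenario, dt = 0.1,
                         initial = c(p_a = 48, p_v = 4), alpha_rc = 1) {
  stopifnot(inherits(params, "physical_params"))
  if (is.character(scenario)) scenario <- scenario_library(scenario)
  stopifnot(inherits(scenario, "cvs_scenario"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  initial <- as.list(initial)
  if (initial$p_a <= initial$p_v || initial$p_v <= 0)
    stop("initial state must satisfy P_a > P_v > 0", call. = FALSE)

  times <- seq(0, scenario$duration, by = dt)
  n <- length(times)
  p_a <- p_v <- numeric(n)
  p_a[1] <- initial$p_a; p_v[1] <- initial$p_v

  ## Drives are piecewise linear, so evaluate them once on the half-step
  ## grid instead of per derivative call.
  half_t <- seq(0, scenario$duration, by = dt / 2)
  dr_all <- .drives_at(scenario, half_t)

  ## Inlined right-hand side (same algebra as pressure_derivatives(),
  ## without per-call validation) for the inner loop.
  kb <- params$k_b; p_set <- params$p_set
  hr_lo <- params$hr_min / 60; hr_span <- (params$hr_max - params$hr_min) / 60
  k_lo <- params$k_min; k_span <- params$k_max - params$k_min
  r_lo <- params$r_min; r_span <- params$r_max - params$r_min
  c_a <- params$c_a; c_v <- params$c_v; d_v_v0 <- params$d_v_v0

  fast_deriv <- function(j, y) {  # j indexes the half-step grid
    pa <- y[1]; pv <- y[2]
    if (pa - pv < MIN_AV_GRADIENT)
      stop("arterial-venous gradient collapsed (P_a - P_v < ",
           MIN_AV_GRADIENT, " mmHg) at t = ", signif(half_t[j], 6), " s",
           call. = FALSE)
    s_b <- 1 / (1 + exp(kb * (pa - p_set)))
    s_tot <- 1 / (1 + exp(-SIGMOID_GAIN * (s_b + dr_all$s[j] - 1)))
    hr <- hr_lo + hr_span * s_tot
    r_mod <- 1 / (1 + exp(-SIGMOID_GAIN * (s_tot + dr_all$m_svr[j])))
    r <- r_lo + r_span * r_mod
    p_p <- (k_lo + k_span * s_tot) * pv / (pa - pv)
    dp_a <- hr * p_p - (pa - pv) / (c_a * r)
    ds_b <- -kb * s_b * (1 - s_b) * dp_a
    ds_tot <- SIGMOID_GAIN * s_tot * (1 - s_tot) * (ds_b + dr_all$s_slope[j])
    dp_v <- (dr_all$i_ex[j] - c_a * dp_a + d_v_v0 * ds_tot) / c_v
    c(dp_a, dp_v)
  }

  y <- c(p_a[1], p_v[1])
  for (i in seq_len(n - 1)) {
    j <- 2L * i - 1L  # half-step grid index of times[i]
    k1 <- fast_deriv(j, y)
    k2 <- fast_deriv(j + 1L, y + dt / 2 * k1)
    k3 <- fast_deriv(j + 1L, y + dt / 2 * k2)
    k4 <- fast_deriv(j + 2L, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (abs(y[1]) > 500 || abs(y[2]) > 500)
      stop("pressure divergence (|P| > 500 mmHg) at t = ",
           signif(times[i + 1], 6), " s", call. = FALSE)
    p_a[i + 1] <- y[1]; p_v[i + 1] <- y[2]
  }

  ## reconstruct the diagnostic (algebraic) states on the saved grid
  dr <- .drives_at(scenario, times)
  s_b <- baroreflex_activation(p_a, params$p_set, params$k_b)
  s_tot <- total_autonomic_activation(s_b, dr$s)
  hr <- heart_rate(s_tot, params$hr_min, params$hr_max)
  r <- peripheral_resistance(resistance_modulation(s_tot, dr$m_svr),
                             params$r_min, params$r_max)
  p_p <- pulse_pressure_model(s_tot, params$k_min, params$k_max, p_a, p_v)

  out <- data.frame(t = times, p_a = p_a, p_v = p_v, hr = hr, p_p = p_p,
                    rc = alpha_rc * params$c_a * r,
                    s_b = s_b, s_tot = s_tot,
                    i_ex = dr$i_ex, m_svr = dr$m_svr, s = dr$s)
  structure(out, class = c("cvs_trace", "data.frame"),
            params = params, scenario = scenario, dt = dt,
            alpha_rc = alpha_rc)
}

#' @export
print.cvs_trace <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("cardiovascular trace: scenario '%s', %d steps of %.3g s\n",
              sc$name, nrow(x), attr(x, "dt")))
  cat(sprintf("  P_a %.1f -> %.1f mmHg | P_v %.2f -> %.2f mmHg | Hr %.0f -> %.0f bpm\n",
              x$p_a[1], x$p_a[nrow(x)], x$p_v[1], x$p_v[nrow(x)],
              x$hr[1], x$hr[nrow(x)]))
  invisible(x)
}

#' @export
plot.cvs_trace <- function(x, ...) {
  old <- graphics::par(mfrow = c(3, 2), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  panels <- list(p_a = "P_a (mmHg)", p_v = "P_v (mmHg)", hr = "Hr (bpm)",
                 p_p = "P_p (mmHg)", rc = "RC (s)", s_b = "S_b")
  for (nm in names(panels)) {
    graphics::plot(x$t / 60, x[[nm]], type = "l", xlab = "time (min)",
                   ylab = panels[[nm]], ...)
  }
  invisible(x)
}

#' Conserved intravascular volume along a trace
#'
#' The pressure-form equations conserve the stressed-volume bookkeeping
#' quantity `V(t) = C_a P_a + C_v P_v - dV_v0 S_tot` (ml, relative to
#' unstressed offsets): its change from the start of the trace must equal
#' the time integral of the external volume rate. Used as an integrator
#' validity oracle.
#'
#' @param trace A `cvs_trace` from [simulate_cvs()].
#' @param params [physical_params()] object; defaults to the set stored in
#'   the trace.
#' @return Numeric series, ml (one value per trace row).
#' @export
conserved_volume <- function(trace, params = attr(trace, "params")) {
  stopifnot(inherits(trace, "cvs_trace"))
  params$c_a * trace$p_a + params$c_v * trace$p_v -
    params$d_v_v0 * trace$s_tot
}

#' Down-sample a trace to the observable grid
#'
#' Extracts the five observable channels at a uniform 10 Hz grid, optionally
#' adding seeded Gaussian measurement noise per channel. This is the
#' noiseless-observables path for estimator studies (the full path goes
#' through waveform synthesis and feature extraction).
#'
#' @param trace A `cvs_trace`.
#' @param fs Target sampling rate, Hz.
#' @param noise_sd Named numeric: standard deviations for any of `p_a, p_v,
#'   hr, p_p, rc` (default: no noise).
#' @param seed Integer seed used when noise is requested.
#' @return An `observable_series` data frame with columns
#'   `t, p_a, p_v, hr, p_p, rc`.
#' @export
trace_observables <- function(trace, fs = 10, noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(trace, "cvs_trace"))
  ## exclusive end point: a D-second trace yields D*fs samples at 0..D-1/fs
  grid <- seq(0, by = 1 / fs, length.out = max(1, floor(max(trace$t) * fs)))
  cols <- c("p_a", "p_v", "hr", "p_p", "rc")
  out <- data.frame(t = grid)
  for (nm in cols)
    out[[nm]] <- stats::approx(trace$t, trace[[nm]], xout = grid, rule = 2)$y
  if (!is.null(noise_sd)) {
    rng <- .seeded_rng(seed)
    for (nm in intersect(names(noise_sd), cols))
      if (noise_sd[[nm]] > 0)
        out[[nm]] <- out[[nm]] + rng$rnorm(length(grid), 0, noise_sd[[nm]])
  }
  as_observable_series(out, fs = fs)
}

## Local RNG stream that does not disturb the global .Random.seed.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  })
  with_state <- function(fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    fun()
  }
  list(
    rnorm = function(n, mean = 0, sd = 1)
      with_state(function() stats::rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1)
      with_state(function() stats::runif(n, min, max)),
    rpois = function(n, lambda)
      with_state(function() stats::rpois(n, lambda))
  )
}
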