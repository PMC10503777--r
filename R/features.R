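#' Detect heart beats in an arterial pressure waveform
#'
#' Locates beat onsets at the diastolic troughs preceding each systolic
#' upstroke. Upstrokes are found where the pressure slope exceeds a
#' data-driven threshold (a fraction of the upper quantile of positive
#' slopes), with a refractory period to suppress double triggers; the onset
#' is then the pressure minimum in the short window before the trigger.
#'
#' @param rec A [waveform_record()], or a numeric arterial pressure vector.
#' @param fs Sampling rate, Hz (taken from the record when given one).
#' @param refractory Minimal inter-beat interval, s.
#' @param slope_frac Threshold as a fraction of the 90th percentile of
#'   positive slopes.
#' @return A beat table: data frame with one row per complete beat and
#'   columns `onset` (s, relative to record start), `period` (s),
#'   `systolic`, `diastolic`, `pulse_pressure` (mmHg).
#' @export
detect_beats <- function(rec, fs = NULL, refractory = 0.2,
                         slope_frac = 0.5) {
  if (inherits(rec, "waveform_record")) {
    p <- rec$abp; fs <- rec$fs
  } else {
    p <- as.numeric(rec)
    if (is.null(fs)) stop("`fs` required for a bare vector", call. = FALSE)
  }
  if (fs < 50) stop("sampling rate must be at least 50 Hz", call. = FALSE)
  if (length(p) < 2 * fs) stop("record must be at least 2 s long", call. = FALSE)

  d <- c(0, diff(p)) * fs
  pos <- d[d > 0]
  empty <- data.frame(onset = numeric(0), period = numeric(0),
                      systolic = numeric(0), diastolic = numeric(0),
                      pulse_pressure = numeric(0))
  if (!length(pos) || stats::quantile(pos, 0.9) < 1e-8) {
    warning("no beats found (flat or non-pulsatile signal)")
    return(empty)
  }
  thr <- slope_frac * stats::quantile(pos, 0.9)

  above <- d > thr
  trig <- which(above & !c(FALSE, above[-length(above)]))
  refr <- round(refractory * fs)
  keep <- logical(length(trig))
  last <- -Inf
  for (i in seq_along(trig)) {
    if (trig[i] - last >= refr) { keep[i] <- TRUE; last <- trig[i] }
  }
  trig <- trig[keep]
  if (length(trig) < 2) {
    warning("no beats found (fewer than two upstrokes)")
    return(empty)
  }

  back <- round(0.15 * fs)
  onsets <- vapply(trig, function(i) {
    j0 <- max(1L, i - back)
    as.integer(j0 + which.min(p[j0:i]) - 1L)
  }, integer(1))
  onsets <- unique(onsets)

  nb <- length(onsets) - 1L
  res <- data.frame(
    onset = (onsets[seq_len(nb)] - 1L) / fs,
    period = diff(onsets) / fs,
    systolic = NA_real_, diastolic = NA_real_
  )
  for (k in seq_len(nb)) {
    idx <- onsets[k]:(onsets[k + 1L] - 1L)
    res$systolic[k] <- max(p[idx])
    res$diastolic[k] <- min(p[idx])
  }
  res$pulse_pressure <- res$systolic - res$diastolic
  res
}

#' Estimate the diastolic decay constant of one beat
#'
#' Windkessel pulse-contour step: the diastolic run-off decays exponentially
#' with time constant `R C_a` (up to the pulse-contour scale). The decay
#' asymptote is first estimated from the lag-1 difference regression
#' (`P[i+1] - P[i]` on `P[i]`, exact for an exponential regardless of its
#' floor), then the decay constant is the slope of the least-squares fit of
#' `log(P - P_floor)` against time. A poor log-linear fit (R-squared below
#' `min_r2`, e.g. non-monotone decay) returns `NA` so the beat can be
#' imputed from its neighbours.
#'
#' @param p Diastolic run-off samples, mmHg (at least 5).
#' @param fs Sampling rate, Hz.
#' @param p_floor Optional known decay asymptote, mmHg; estimated per beat
#'   when `NULL`.
#' @param min_r2 Acceptance threshold on the log-linear fit.
#' @return Decay constant, s, with attribute `r2`; `NA` when the fit fails.
#' @export
estimate_rc <- function(p, fs, p_floor = NULL, min_r2 = 0.5) {
  p <- as.numeric(p)
  if (length(p) < 5) return(structure(NA_real_, r2 = NA_real_))
  dt <- 1 / fs
  if (is.null(p_floor)) {
    dp <- diff(p)
    fit0 <- stats::lm.fit(cbind(1, p[-length(p)]), dp)
    rho <- 1 + fit0$coefficients[2]
    p_floor <- if (is.finite(rho) && rho > 0 && rho < 1)
      fit0$coefficients[1] / (1 - rho)
    else
      min(p) - 0.05 * max(diff(range(p)), 1)
  }
  if (min(p) <= p_floor)
    p_floor <- min(p) - 0.05 * max(diff(range(p)), 1)
  y <- log(p - p_floor)
  tt <- (seq_along(p) - 1) * dt
  fit <- stats::lm.fit(cbind(1, tt), y)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / max(sum((y - mean(y))^2), 1e-12)
  if (!is.finite(slope) || slope >= 0 || r2 < min_r2)
    return(structure(NA_real_, r2 = r2))
  structure(-1 / slope, r2 = r2)
}

#' Clamp outliers to local robust thresholds
#'
#' Points lying more than `k` local scaled median absolute deviations from
#' the local median (within a sliding time window) are replaced by the
#' violated threshold itself: values below `median - k * MAD` become the
#' lower threshold, values above `median + k * MAD` the upper one. When the
#' local MAD degenerates to zero it is floored at `mad_floor` so that an
#' identical-valued window does not clamp everything.
#'
#' @param x Numeric series.
#' @param t Sample times, s (defaults to an index grid; may be irregular,
#'   e.g. beat onsets).
#' @param window Sliding window length, s.
#' @param k Threshold multiplier.
#' @param mad_floor Lower bound on the scaled MAD (series units).
#' @return Clamped series, same length as `x`.
#' @export
replace_outliers <- function(x, t = seq_along(x), window = 20, k = 3,
                             mad_floor = 0.5) {
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  n <- length(x)
  if (n == 0) return(x)
  half <- window / 2
  lo_idx <- findInterval(t - half, t) + 1L
  hi_idx <- findInterval(t + half, t)
  out <- x
  for (i in seq_len(n)) {
    w <- x[lo_idx[i]:hi_idx[i]]
    med <- stats::median(w)
    s <- max(stats::mad(w, center = med), mad_floor)
    lo <- med - k * s; hi <- med + k * s
    if (x[i] < lo) out[i] <- lo else if (x[i] > hi) out[i] <- hi
  }
  out
}

#' Resample beat-wise and slow features onto the uniform observable grid
#'
#' Linear interpolation of the five channels onto a uniform grid (default
#' 10 Hz): mean pressures come from moving averages of the raw channels,
#' beat-wise channels (heart rate, pulse pressure, RC) are interpolated from
#' their beat mid-times. An optional low-pass stage (Butterworth, applied
#' forward-backward) can be enabled with `lp_cutoff`; the default is
#' pass-through.
#'
#' @param beats Beat table with an `rc` column (see [detect_beats()],
#'   [estimate_rc()]).
#' @param slow Data frame with columns `t`, `p_a`, `p_v`: the slow-timescale
#'   mean pressures.
#' @param duration Record length, s.
#' @param fs_out Output rate, Hz.
#' @param lp_cutoff Optional low-pass cutoff, Hz (must be below the output
#'   Nyquist rate); `NULL` disables the filter.
#' @return An `observable_series`.
#' @export
resample_and_filter <- function(beats, slow, duration, fs_out = 10,
                                lp_cutoff = NULL) {
  if (!nrow(beats)) stop("beat table is empty", call. = FALSE)
  grid <- seq(0, by = 1 / fs_out, length.out = max(1, floor(duration * fs_out)))
  mid <- beats$onset + beats$period / 2
  interp <- function(xt, xv)
    stats::approx(xt, xv, xout = grid, rule = 2)$y
  out <- data.frame(
    t = grid,
    p_a = interp(slow$t, slow$p_a),
    p_v = interp(slow$t, slow$p_v),
    hr = interp(mid, 60 / beats$period),
    p_p = interp(mid, beats$pulse_pressure),
    rc = interp(mid, beats$rc)
  )
  if (!is.null(lp_cutoff)) {
    if (lp_cutoff >= fs_out / 2)
      stop("`lp_cutoff` must be below the output Nyquist rate (",
           fs_out / 2, " Hz)", call. = FALSE)
    bf <- signal::butter(2, lp_cutoff / (fs_out / 2), type = "low")
    for (nm in c("p_a", "p_v", "hr", "p_p", "rc"))
      out[[nm]] <- as.numeric(signal::filtfilt(bf, out[[nm]]))
  }
  as_observable_series(out, fs = fs_out)
}

#' Validity screen for an observable segment
#'
#' A segment is analyzable only when every sample satisfies the
#' physiological plausibility ranges: 20 < P_a < 250 mmHg,
#' 0 < P_v < 25 mmHg, RC > 0, 30 < Hr < 250 beats/min and P_p > 10 mmHg.
#' The first violated criterion (in that order) is reported.
#'
#' @param seg An `observable_series` (or compatible data frame) covering the
#'   segment.
#' @return List with `valid` (logical) and `reason` (`NA` when valid).
#' @export
validate_segment <- function(seg) {
  checks <- list(
    `arterial pressure` = all(seg$p_a > 20 & seg$p_a < 250),
    `venous pressure` = all(seg$p_v > 0 & seg$p_v < 25),
    resistance = all(seg$rc > 0),
    `heart rate` = all(seg$hr > 30 & seg$hr < 250),
    `pulse pressure` = all(seg$p_p > 10)
  )
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad)) list(valid = FALSE, reason = bad[1])
  else list(valid = TRUE, reason = NA_character_)
}

.moving_average <- function(x, n) {
  ## centered moving mean with shrinking windows at the edges
  n <- max(1L, as.integer(n))
  if (n %% 2 == 0) n <- n + 1L
  cs <- cumsum(c(0, x))
  half <- (n - 1L) %/% 2L
  i <- seq_along(x)
  lo <- pmax(i - half, 1L); hi <- pmin(i + half, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Extract the five observables from a pressure waveform record
#'
#' Full feature-extraction pipeline: beat detection on the arterial channel,
#' per-beat Windkessel decay-constant estimation, robust outlier clamping of
#' every channel, and resampling onto the uniform 10 Hz observable grid.
#' Mean arterial and venous pressures are moving averages (default 10 s) of
#' the raw channels; heart rate, pulse pressure and RC come from the beat
#' table. Deterministic.
#'
#' @param rec A [waveform_record()].
#' @param fs_out Output rate, Hz.
#' @param mean_window Moving-average window for the mean pressures, s.
#' @param outlier_window,outlier_k Outlier clamp parameters (see
#'   [replace_outliers()]).
#' @param lp_cutoff Optional low-pass cutoff, Hz (default: pass-through).
#' @return An `observable_series` with time measured from the record start.
#' @export
extract_observables <- function(rec, fs_out = 10, mean_window = 10,
                                outlier_window = 20, outlier_k = 3,
                                lp_cutoff = NULL) {
  stopifnot(inherits(rec, "waveform_record"))
  if (length(rec$abp) < 10 * rec$fs)
    stop("record must be at least 10 s long", call. = FALSE)
  if (all(!is.finite(rec$cvp)) || !length(rec$cvp))
    stop("venous channel is empty", call. = FALSE)

  beats <- detect_beats(rec)
  if (!nrow(beats)) stop("no beats detected", call. = FALSE)

  ## per-beat Windkessel decay constant from the diastolic run-off
  fs <- rec$fs
  rc <- rep(NA_real_, nrow(beats))
  for (k in seq_len(nrow(beats))) {
    i0 <- round(beats$onset[k] * fs) + 1L
    i1 <- i0 + round(beats$period[k] * fs) - 1L
    seg <- rec$abp[i0:min(i1, length(rec$abp))]
    pk <- which.max(seg)
    runoff <- seg[min(pk + 2L, length(seg)):length(seg)]
    rc[k] <- as.numeric(estimate_rc(runoff, fs))
  }
  if (all(is.na(rc)))
    stop("diastolic decay fit failed on every beat", call. = FALSE)
  if (anyNA(rc)) {  # impute flagged beats from neighbours
    ok <- which(!is.na(rc))
    rc <- stats::approx(beats$onset[ok], rc[ok], xout = beats$onset,
                        rule = 2)$y
  }
  beats$rc <- rc

  ## outlier clamping per channel (beat-wise fast channels, then the
  ## slow mean-pressure channels on the raw grid decimated to fs_out)
  mid <- beats$onset + beats$period / 2
  hr_bpm <- replace_outliers(60 / beats$period, mid, outlier_window,
                             outlier_k, mad_floor = 1)
  beats$period <- 60 / hr_bpm
  beats$pulse_pressure <- replace_outliers(beats$pulse_pressure, mid,
                                           outlier_window, outlier_k,
                                           mad_floor = 0.5)
  beats$rc <- replace_outliers(beats$rc, mid, outlier_window, outlier_k,
                               mad_floor = 0.05)

  duration <- (length(rec$abp) - 1L) / fs
  tt <- (seq_along(rec$abp) - 1L) / fs
  dec <- seq(1L, length(tt), by = max(1L, round(fs / fs_out)))
  slow <- data.frame(
    t = tt[dec],
    p_a = .moving_average(rec$abp, mean_window * fs)[dec],
    p_v = .moving_average(rec$cvp, mean_window * fs)[dec]
  )
  slow$p_a <- replace_outliers(slow$p_a, slow$t, outlier_window, outlier_k,
                               mad_floor = 0.5)
  slow$p_v <- replace_outliers(slow$p_v, slow$t, outlier_window, outlier_k,
                               mad_floor = 0.5)

  resample_and_filter(beats, slow, duration, fs_out = fs_out,
                      lp_cutoff = lp_cutoff)
}
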