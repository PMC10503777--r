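#' Waveform record container
#'
#' Beat-resolved arterial and venous pressure traces at a fixed sampling
#' rate (default 125 Hz), as produced by bedside pressure transducers or by
#' the package's synthesizer.
#'
#' @param abp,cvp Arterial and venous pressure samples, mmHg (equal length).
#' @param fs Sampling rate, Hz.
#' @param t0 Start time, s.
#' @param artifact_mask Optional logical vector marking injected artifacts.
#' @return Object of class `waveform_record`.
#' @export
waveform_record <- function(abp, cvp, fs = 125, t0 = 0,
                            artifact_mask = NULL) {
  if (length(abp) != length(cvp))
    stop("arterial and venous channels must have equal length", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  structure(list(abp = abp, cvp = cvp, fs = fs, t0 = t0,
                 artifact_mask = artifact_mask),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("waveform record: %d samples at %g Hz (%.1f s), t0 = %g s\n",
              length(x$abp), x$fs, length(x$abp) / x$fs, x$t0))
  if (!is.null(x$artifact_mask))
    cat(sprintf("  artifact mask covers %d samples\n", sum(x$artifact_mask)))
  invisible(x)
}

#' @rdname waveform_record
#' @export
record_times <- function(x) {
  stopifnot(inherits(x, "waveform_record"))
  x$t0 + (seq_along(x$abp) - 1L) / x$fs
}

#' Synthesize pressure waveforms from observables
#'
#' Inverse of the feature-extraction pipeline: builds a 125 Hz two-channel
#' pressure record whose per-beat statistics reproduce a given observable
#' series. Each beat of period `60/Hr` consists of a raised half-cosine
#' systolic upstroke over a fixed ejection fraction of the cycle followed by
#' an exponential diastolic run-off with time constant `RC / alpha_rc`.
#' The systolic peak and decay asymptote are solved per beat so that the
#' beat's peak-to-trough range equals the pulse pressure and its time
#' average equals the mean arterial pressure. The venous channel is the mean
#' venous pressure plus small cardiac and respiratory oscillations.
#'
#' The pulse morphology is a modelling choice: any shape whose per-beat
#' mean, range, rate and decay constant match the observables serves the
#' round-trip contract equally well.
#'
#' @param obs An `observable_series`.
#' @param fs Sampling rate, Hz (default 125).
#' @param ejection_frac Fraction of the cycle spent in systole.
#' @param alpha_rc True pulse-contour scale encoded in the record: the
#'   diastolic time constant is `rc / alpha_rc`.
#' @param venous_cardiac_amp,venous_resp_amp Amplitudes (mmHg) of the venous
#'   oscillations; respiratory frequency is fixed at 0.25 Hz.
#' @param noise_sd Named numeric with optional additive Gaussian noise
#'   standard deviations for `abp` and `cvp`, mmHg (default: none).
#' @param seed Integer seed (noise is deterministic given the seed).
#' @return A [waveform_record()].
#' @export
synthesize_waveforms <- function(obs, fs = 125, ejection_frac = 0.3,
                                 alpha_rc = 1,
                                 venous_cardiac_amp = 0.8,
                                 venous_resp_amp = 0.4,
                                 noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(obs, "observable_series"))
  if (any(obs$hr <= 0)) stop("heart rate must be positive", call. = FALSE)
  if (any(obs$p_p < 0)) stop("pulse pressure must be nonnegative", call. = FALSE)
  if (fs <= 2 * max(obs$hr) / 60)
    stop("sampling rate must exceed twice the maximal heart frequency",
         call. = FALSE)

  duration <- max(obs$t)
  n <- floor(duration * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs
  at <- function(chan, t) stats::approx(obs$t, obs[[chan]], xout = t,
                                        rule = 2)$y
  abp <- numeric(n)

  t_k <- 0
  while (t_k < duration) {
    period <- 60 / at("hr", t_k)
    pa <- at("p_a", t_k); pp <- at("p_p", t_k)
    tau <- at("rc", t_k) / alpha_rc
    t_sys <- ejection_frac * period
    t_dia <- period - t_sys
    a <- 1 - exp(-t_dia / tau)
    amp <- pp / a                       # P_s - P_inf
    p_s <- pa + ejection_frac * pp / 2 +
      (1 - ejection_frac) * amp * (1 - (tau / t_dia) * a)
    p_inf <- p_s - amp
    p_d <- p_s - pp

    idx <- which(tt >= t_k & tt < min(t_k + period, duration + 1 / fs))
    if (length(idx)) {
      u <- tt[idx] - t_k
      sys <- u < t_sys
      abp[idx[sys]] <- p_d + (p_s - p_d) * (1 - cos(pi * u[sys] / t_sys)) / 2
      abp[idx[!sys]] <- p_inf + amp * exp(-(u[!sys] - t_sys) / tau)
    }
    t_k <- t_k + period
  }

  pv <- at("p_v", tt)
  cvp <- pv + venous_cardiac_amp * sin(2 * pi * tt * at("hr", tt) / 60) +
    venous_resp_amp * sin(2 * pi * 0.25 * tt)

  if (!is.null(noise_sd)) {
    noise_sd <- as.list(noise_sd)
    rng <- .seeded_rng(seed)
    if (!is.null(noise_sd$abp) && noise_sd$abp > 0)
      abp <- abp + rng$rnorm(n, 0, noise_sd$abp)
    if (!is.null(noise_sd$cvp) && noise_sd$cvp > 0)
      cvp <- cvp + rng$rnorm(n, 0, noise_sd$cvp)
  }
  waveform_record(abp, cvp, fs = fs, t0 = 0)
}

#' Inject measurement artifacts into a waveform record
#'
#' Adds the three artifact families seen in bedside recordings: transient
#' pressure spikes, flat-line dropouts (transducer flushing or clotting) and
#' slow baseline wander (patient movement). Spike and dropout onsets are
#' drawn from seeded Poisson processes. Returns a new record carrying a
#' ground-truth mask of artifact-affected samples.
#'
#' @param rec A [waveform_record()].
#' @param spike_rate Spikes per second (Poisson rate).
#' @param spike_amp Spike amplitude, mmHg.
#' @param dropout_rate Dropouts per second (Poisson rate).
#' @param dropout_dur Dropout duration, s.
#' @param wander_amp Baseline wander amplitude, mmHg.
#' @param wander_period Wander period, s.
#' @param seed Integer seed.
#' @return A [waveform_record()] with `artifact_mask` set.
#' @export
inject_artifacts <- function(rec, spike_rate = 0, spike_amp = 100,
                             dropout_rate = 0, dropout_dur = 2,
                             wander_amp = 0, wander_period = 60,
                             seed = 1L) {
  stopifnot(inherits(rec, "waveform_record"))
  if (spike_rate < 0 || dropout_rate < 0 || dropout_dur < 0)
    stop("artifact rates and durations must be nonnegative", call. = FALSE)
  n <- length(rec$abp)
  abp <- rec$abp
  mask <- logical(n)
  rng <- .seeded_rng(seed)
  dur_s <- n / rec$fs

  if (spike_rate > 0) {
    k <- rng$rpois(1, spike_rate * dur_s)
    if (k > 0) {
      at <- pmax(1L, pmin(n, ceiling(rng$runif(k, 0, dur_s) * rec$fs)))
      abp[at] <- abp[at] + spike_amp
      mask[at] <- TRUE
    }
  }
  if (dropout_rate > 0) {
    k <- rng$rpois(1, dropout_rate * dur_s)
    if (k > 0) {
      starts <- pmax(1L, pmin(n, ceiling(rng$runif(k, 0, dur_s) * rec$fs)))
      len <- round(dropout_dur * rec$fs)
      for (s0 in starts) {
        idx <- s0:min(n, s0 + len - 1L)
        abp[idx] <- abp[s0]
        mask[idx] <- TRUE
      }
    }
  }
  if (wander_amp > 0) {
    tt <- (seq_len(n) - 1L) / rec$fs
    abp <- abp + wander_amp * sin(2 * pi * tt / wander_period)
    mask <- mask | rep(TRUE, n)  # wander touches every sample
  }
  waveform_record(abp, rec$cvp, fs = rec$fs, t0 = rec$t0,
                  artifact_mask = mask)
}

#' Read / write waveform records
#'
#' Two-channel columnar text interchange: CSV with a
#' `# cvstate waveform v1` header comment and columns `t, abp, cvp`.
#'
#' @param rec A [waveform_record()].
#' @param path File path.
#' @return `write_waveform` returns `path` invisibly; `read_waveform` a
#'   [waveform_record()].
#' @export
write_waveform <- function(rec, path) {
  stopifnot(inherits(rec, "waveform_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cvstate waveform v1 fs=%g", rec$fs), con)
  tt <- rec$t0 + (seq_along(rec$abp) - 1L) / rec$fs
  utils::write.csv(data.frame(t = tt, abp = rec$abp, cvp = rec$cvp),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  header <- readLines(path, n = 1)
  fs <- NULL
  if (grepl("^# cvstate waveform", header)) {
    m <- regmatches(header, regexpr("fs=[0-9.]+", header))
    if (length(m)) fs <- as.numeric(sub("fs=", "", m))
  }
  x <- utils::read.csv(path, comment.char = "#")
  miss <- setdiff(c("t", "abp", "cvp"), names(x))
  if (length(miss))
    stop("waveform file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(fs)) fs <- 1 / stats::median(diff(x$t))
  waveform_record(x$abp, x$cvp, fs = fs, t0 = x$t[1])
}
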