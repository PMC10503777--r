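test_that("beat detection tracks a rate switch and rejects flat signals", {
  ## two concatenated rates: 80 then 160 bpm
  t1 <- seq(0, 29.9, by = 0.1); t2 <- seq(30, 59.9, by = 0.1)
  obs <- as_observable_series(
    data.frame(t = c(t1, t2), p_a = 100, p_v = 5,
               hr = c(rep(80, length(t1)), rep(160, length(t2))),
               p_p = 40, rc = 1), fs = 10)
  rec <- synthesize_waveforms(obs)
  beats <- detect_beats(rec)
  hr_beat <- 60 / beats$period
  early <- hr_beat[beats$onset < 28]
  late <- hr_beat[beats$onset > 32]
  expect_equal(mean(early), 80, tolerance = 0.02)
  expect_equal(mean(late), 160, tolerance = 0.02)
  ## the transition is crossed within two beats
  mid <- beats$onset[hr_beat > 100][1]
  expect_lt(mid - 30, 2 * 60 / 80)

  expect_warning(flatb <- detect_beats(rep(80, 1000), fs = 125), "no beats")
  expect_equal(nrow(flatb), 0)
  expect_error(detect_beats(rep(1, 10), fs = 125), "2 s")
  expect_error(detect_beats(1:1000), "fs")
})

test_that("diastolic decay estimator recovers exponential time constants", {
  fs <- 125
  tt <- seq(0, 0.4, by = 1 / fs)
  p <- 40 + 80 * exp(-tt / 0.9)
  expect_equal(as.numeric(estimate_rc(p, fs)), 0.9, tolerance = 0.01)
  ## scale equivariance: doubling tau doubles the estimate
  p2 <- 40 + 80 * exp(-tt / 1.8)
  expect_equal(as.numeric(estimate_rc(p2, fs)),
               2 * as.numeric(estimate_rc(p, fs)), tolerance = 0.01)
  ## exact for an unknown non-venous asymptote too
  p3 <- -35 + 150 * exp(-tt / 1.2)
  expect_equal(as.numeric(estimate_rc(p3, fs)), 1.2, tolerance = 0.01)
  ## non-monotone rubbish is flagged
  set.seed(2)
  expect_true(is.na(estimate_rc(rnorm(30, 80, 5), fs)))
  expect_true(is.na(estimate_rc(c(80, 70, 60), fs)))  # too short
})

test_that("synthesized decay constant is recovered within 15 percent", {
  obs <- const_obs(60, rc = 1.2)
  rec <- synthesize_waveforms(obs)
  ex <- extract_observables(rec)
  mid <- ex$rc[ex$t > 10 & ex$t < 50]
  expect_true(all(abs(mid - 1.2) / 1.2 < 0.15))
})

test_that("outlier clamping follows the local median rule", {
  ## constant series: unchanged
  x <- rep(5, 100)
  expect_equal(replace_outliers(x, seq(0, 9.9, 0.1)), x)

  ## a large spike in noise is clamped to the upper threshold, not removed
  set.seed(3)
  t <- seq(0, 9.9, 0.1)
  x <- rnorm(100, 50, 1)
  x[50] <- 50 + 30
  y <- replace_outliers(x, t, window = 4, k = 3, mad_floor = 0.01)
  expect_lt(y[50], x[50])
  expect_gt(y[50], 50)          # clamped to threshold, not to the median
  expect_equal(y[-50], x[-50])  # everything else untouched

  ## all-identical-but-one: zero MAD floored, spike still clamped
  z <- rep(10, 50); z[25] <- 30
  w <- replace_outliers(z, seq(0, 4.9, 0.1), window = 2, k = 3,
                        mad_floor = 0.5)
  expect_equal(w[25], 10 + 3 * 0.5)
  expect_equal(w[-25], z[-25])
})

test_that("outlier clamping is idempotent up to threshold recomputation", {
  set.seed(4)
  t <- seq(0, 59.9, 0.1)
  x <- rnorm(600, 100, 2) + 10 * (runif(600) < 0.02)
  y1 <- replace_outliers(x, t)
  y2 <- replace_outliers(y1, t)
  expect_lt(max(abs(y2 - y1)), 0.5)
})

test_that("resampling interpolates beat-wise values onto the 10 Hz grid", {
  beats <- data.frame(onset = c(0, 0.5, 1.1, 1.6), period = c(0.5, 0.6, 0.5, 0.5),
                      systolic = 120, diastolic = 80, pulse_pressure = 40,
                      rc = c(1, 1.2, 1.1, 1))
  slow <- data.frame(t = seq(0, 2, 0.1), p_a = 100, p_v = 5)
  out <- resample_and_filter(beats, slow, duration = 2)
  expect_s3_class(out, "observable_series")
  expect_equal(nrow(out), 20)
  expect_equal(out$p_a, rep(100, 20))
  ## linear interpolation between beat mid-times
  mids <- beats$onset + beats$period / 2
  expect_equal(out$rc[out$t == 0.9],
               approx(mids, beats$rc, xout = 0.9)$y)
  expect_error(resample_and_filter(beats[0, ], slow, 2), "empty")
  ## a sub-Nyquist cutoff is accepted, a super-Nyquist one refused
  expect_error(resample_and_filter(beats, slow, 2, lp_cutoff = 7),
               "Nyquist")
  smooth <- resample_and_filter(beats, slow, 2, lp_cutoff = 2)
  expect_equal(mean(smooth$p_a), 100, tolerance = 0.1)
})

test_that("slow oscillations survive the default (pass-through) filter", {
  t <- seq(0, 299.9, by = 0.1)
  obs <- as_observable_series(
    data.frame(t = t, p_a = 100 + 5 * sin(2 * pi * 0.01 * t), p_v = 5,
               hr = 120, p_p = 40, rc = 1), fs = 10)
  rec <- synthesize_waveforms(obs)
  ex <- extract_observables(rec)
  mid <- ex$t > 20 & ex$t < 280
  truth <- 100 + 5 * sin(2 * pi * 0.01 * ex$t[mid])
  ## the 10-s moving average attenuates a 100-s sine by sinc(0.1) ~ 0.984
  expect_gt(cor(ex$p_a[mid], truth), 0.99)
  expect_gt(diff(range(ex$p_a[mid])), 9)
})

test_that("segment validity screen reports the first violated criterion", {
  good <- const_obs(300)
  expect_true(validate_segment(good)$valid)

  low_pp <- good; low_pp$p_p[17] <- 8
  v <- validate_segment(low_pp)
  expect_false(v$valid)
  expect_equal(v$reason, "pulse pressure")

  high_pv <- good; high_pv$p_v[100] <- 30
  expect_equal(validate_segment(high_pv)$reason, "venous pressure")

  low_pa <- good; low_pa$p_a[1] <- 15
  expect_equal(validate_segment(low_pa)$reason, "arterial pressure")

  bad_hr <- good; bad_hr$hr[5] <- 20
  expect_equal(validate_segment(bad_hr)$reason, "heart rate")

  bad_rc <- good; bad_rc$rc[9] <- -0.1
  expect_equal(validate_segment(bad_rc)$reason, "resistance")
})

test_that("extraction round trip meets the channel tolerances", {
  tr <- simulate_cvs(neonate_params(),
                     cvs_scenario("drift", 120,
                                  i_ex = schedule(c(0, 120), c(0, -0.06))))
  obs <- trace_observables(tr)
  rec <- synthesize_waveforms(obs, alpha_rc = 1.3)
  ex <- extract_observables(rec)
  keep <- ex$t > 8 & ex$t < 110
  relerr <- function(chan) {
    truth <- approx(obs$t, obs[[chan]], xout = ex$t[keep])$y
    max(abs(ex[[chan]][keep] - truth) / truth)
  }
  expect_lt(relerr("p_a"), 0.02)
  expect_lt(relerr("p_v"), 0.02)
  expect_lt(relerr("hr"), 0.02)
  expect_lt(relerr("p_p"), 0.05)
  ## RC up to a global scale (absorbed by the pulse-contour constant)
  truth_rc <- approx(obs$t, obs$rc, xout = ex$t[keep])$y
  ratio <- ex$rc[keep] / truth_rc
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.15)
})

test_that("extracted channels are invariant to a record time offset", {
  obs <- const_obs(30, hr = 110)
  rec <- synthesize_waveforms(obs)
  shifted <- waveform_record(rec$abp, rec$cvp, fs = rec$fs, t0 = 137)
  a <- extract_observables(rec)
  b <- extract_observables(shifted)
  expect_equal(a$p_a, b$p_a)
  expect_equal(a$hr, b$hr)
  expect_equal(a$rc, b$rc)
})

test_that("integrated heart rate counts the beats", {
  obs <- const_obs(60, hr = 132)
  rec <- synthesize_waveforms(obs)
  beats <- detect_beats(rec)
  ex <- extract_observables(rec)
  integrated <- sum(ex$hr / 60) * 0.1
  expect_lt(abs(integrated - nrow(beats)), 2)
})

test_that("artifact clamping reduces extraction error", {
  obs <- const_obs(60)
  rec <- synthesize_waveforms(obs)
  bad <- inject_artifacts(rec, spike_rate = 0.2, spike_amp = 80, seed = 3)
  clamped <- extract_observables(bad)
  raw <- extract_observables(bad, outlier_k = 1e9)  # clamping disabled
  expect_lt(max(abs(clamped$p_p - 40)), max(abs(raw$p_p - 40)))
})

test_that("extraction input guards", {
  obs <- const_obs(30)
  rec <- synthesize_waveforms(obs)
  short <- waveform_record(rec$abp[1:500], rec$cvp[1:500])
  expect_error(extract_observables(short), "10 s")
  no_venous <- waveform_record(rec$abp, rep(NA_real_, length(rec$cvp)))
  expect_error(extract_observables(no_venous), "venous")
})
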