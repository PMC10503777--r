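test_that("age-bracketed bounds match the normative tables", {
  b <- build_bounds(neonate_meta())
  expect_equal(unlist(b["p_set", ]), c(lo = 42, hi = 73))
  expect_equal(unlist(b["hr_min", ]), c(lo = 110, hi = 130))
  expect_equal(unlist(b["hr_max", ]), c(lo = 150, hi = 180))
  expect_equal(b["k_max_rel", "hi"], 200 / 0.02)
  expect_equal(b["k_max_rel", "lo"], 50 / 0.15, tolerance = 1e-12)
  ## the printed neonatal simulation values sit inside the volume bounds
  expect_gt(65 / 0.45, b["d_v_v0_rel", "lo"])
  expect_lt(65 / 0.45, b["d_v_v0_rel", "hi"])

  b12 <- build_bounds(patient_meta(12, 40))
  expect_equal(unlist(b12["p_set", ]), c(lo = 59, hi = 89))
  expect_equal(unlist(b12["hr_max", ]), c(lo = 115, hi = 160))
  expect_equal(unlist(b12["hr_min", ]), c(lo = 60, hi = 90))
  ## volume bounds are weight-independent in the scaled parameterization
  b12b <- build_bounds(patient_meta(12, 80))
  expect_equal(b12$lo, b12b$lo)
  expect_true(all(b$lo < b$hi))
})

test_that("observed extremes tighten the rate bounds monotonically", {
  b <- build_bounds(patient_meta(2, 12))  # Hr_min bracket [80, 110]
  obs <- const_obs(30, hr = 95, rc = 1.5)
  obs$hr[3] <- 140
  b2 <- update_bounds_from_observables(b, obs)
  expect_equal(b2["hr_min", "hi"], 95)
  expect_equal(b2["hr_min", "lo"], 80)
  expect_equal(b2["hr_max", "lo"], 140)
  ## no new extrema: unchanged
  b3 <- update_bounds_from_observables(b2, obs)
  expect_equal(b3, b2)
  ## RC analogue: observed max raises the lower bound of the range top
  obs2 <- const_obs(30, rc = 2.8)
  b4 <- update_bounds_from_observables(b, obs2)
  expect_equal(b4["r_max_scaled", "lo"], 2.8)
  expect_equal(b4["r_min_scaled", "hi"], 2.5)  # min(2.5, 2.8) unchanged
  ## an extremum that empties an interval widens it with a warning
  low <- const_obs(30, hr = 100)
  bn <- build_bounds(neonate_meta())  # Hr_min bracket [110, 130]
  expect_warning(b5 <- update_bounds_from_observables(bn, low), "widening")
  expect_lt(b5["hr_min", "lo"], b5["hr_min", "hi"])
})

test_that("segmentation yields the printed window counts", {
  obs25 <- trace_observables(scenario_trace("control"))  # 25 minutes
  w <- segment_series(obs25)
  expect_equal(nrow(w), 12)
  expect_equal(w$start, seq(0, 1100, by = 100))
  expect_true(all(w$valid))

  one <- const_obs(300)
  expect_equal(nrow(segment_series(one)), 1)

  expect_warning(none <- segment_series(const_obs(299)), "shorter")
  expect_equal(nrow(none), 0)
})

test_that("invalid windows are flagged with their reason", {
  obs <- const_obs(500)
  obs$p_p[obs$t > 350] <- 8
  w <- segment_series(obs)
  expect_true(w$valid[1])          # [0, 300): clean
  expect_false(w$valid[2])         # [100, 400): catches the drop
  expect_equal(w$reason[2], "pulse pressure")
})

test_that("residuals vanish at the generating parameters", {
  obs <- ramp_window("distributive")
  seg <- obs[obs$t < 300, ]
  ## truth over this window: S = 0.2 constant, M ramps -1/6 -> -1/3
  th <- as_scaled_params(neonate_params(), i_ex = 0, s_const = 0.2,
                         m_const = -1 / 6, m_slope = -0.5 / 900,
                         alpha_rc = 1)
  ct <- cost_terms(seg, th)
  expect_lt(max(abs(ct$f_h)), 1e-6)
  expect_lt(max(abs(ct$f_r)), 1e-6)
  expect_lt(max(abs(ct$f_p)), 1e-6)
  ## derivative-bearing terms are limited by derivative estimation and
  ## shrink with the smoothing window
  expect_lt(sqrt(mean(ct$f_i^2)), 0.05)
  ct_short <- cost_terms(seg, th, cost_config(deriv_window = 10))
  expect_lt(sqrt(mean(ct_short$f_i^2)), sqrt(mean(ct$f_i^2)))
  expect_lt(sqrt(mean(ct$f_a^2)), 0.05)
})

test_that("heart-rate residual is linear in the rate ceiling", {
  obs <- ramp_window("hypovolemic")
  seg <- obs[obs$t < 300, ]
  th <- as_scaled_params(neonate_params(), s_const = 0.2)
  th2 <- th; th2$hr_max <- th$hr_max + 10
  a <- cost_terms(seg, th)
  b <- cost_terms(seg, th2)
  ## shift equals 10 * S_tot(t) at every sample
  s_tot <- (b$f_h - a$f_h) / 10
  expect_true(all(s_tot > 0 & s_tot < 1))
  hr_model <- th$hr_min + (th$hr_max - th$hr_min) * s_tot
  expect_equal(hr_model, seg$hr + a$f_h, tolerance = 1e-8)
})

test_that("vectorized objective matches the straight-loop oracle", {
  obs <- ramp_window("hypovolemic")
  seg <- obs[obs$t < 300, ]
  cfg <- cost_config()
  b <- build_bounds(neonate_meta())
  sd <- cvstate:::.segment_data(as_observable_series(seg, 10), 0, 300,
                                cfg, b)
  hist <- data.frame(start = c(-300, -200))
  set.seed(21)
  for (p in cvstate:::PARAM_NAMES)
    hist[[p]] <- runif(2, b[p, "lo"], b[p, "hi"])
  for (draw in 1:25) {
    th <- b$lo + runif(15) * (b$hi - b$lo)
    names(th) <- cvstate:::PARAM_NAMES
    j_vec <- segment_objective(seg, th, cfg, hist, b)
    j_loop <- naive_objective(seg, th, cfg, hist, b, sd$dpa, sd$dpv)
    expect_equal(j_vec, j_loop, tolerance = 1e-10)
  }
  ## beta = 0 drops the history penalty
  cfg0 <- cost_config(beta = 0)
  th <- b$lo + 0.5 * (b$hi - b$lo); names(th) <- cvstate:::PARAM_NAMES
  expect_equal(segment_objective(seg, th, cfg0, hist, b),
               segment_objective(seg, th, cfg0, NULL, b), tolerance = 1e-12)
})

test_that("objective gradient matches central finite differences", {
  obs <- ramp_window("combined")
  seg <- obs[obs$t < 300, ]
  cfg <- cost_config()
  b <- build_bounds(neonate_meta())
  sd <- cvstate:::.segment_data(as_observable_series(seg, 10), 0, 300,
                                cfg, b)
  set.seed(31)
  th_vec <- b$lo + runif(15) * (b$hi - b$lo)
  th <- cvstate:::.theta_vec_to_list(th_vec)
  ga <- cvstate:::.objective_gradient(sd, th, cfg, NULL, b)
  gn <- vapply(1:15, function(i) {
    h <- max(1e-6 * abs(th_vec[i]), 1e-9)
    up <- th_vec; up[i] <- up[i] + h
    dn <- th_vec; dn[i] <- dn[i] - h
    (cvstate:::.objective_value(sd, cvstate:::.theta_vec_to_list(up), cfg,
                                NULL, b) -
       cvstate:::.objective_value(sd, cvstate:::.theta_vec_to_list(dn), cfg,
                                  NULL, b)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(ga), gn, tolerance = 1e-4)
})

test_that("segment estimation is seeded, bounded, and improves with restarts", {
  obs <- ramp_window("hypovolemic")
  seg <- obs[obs$t < 300, ]
  b <- update_bounds_from_observables(build_bounds(neonate_meta()), obs)
  cfg <- cost_config(maxit = 200)
  e1 <- estimate_segment(seg, b, cfg, n_starts = 1, seed = 5)
  e5 <- estimate_segment(seg, b, cfg, n_starts = 5, seed = 5)
  e5b <- estimate_segment(seg, b, cfg, n_starts = 5, seed = 5)
  expect_identical(e5$theta, e5b$theta)        # determinism
  expect_lte(e5$cost, e1$cost)                 # min over a superset
  expect_equal(e5$restarts[1], e1$restarts[1]) # shared seed stream
  expect_true(all(e5$theta >= b$lo - 1e-9 & e5$theta <= b$hi + 1e-9))
  expect_error(estimate_segment(seg, b, cfg, n_starts = 0), "at least 1")
})

test_that("estimate_trace smooths, and a single segment passes through", {
  obs <- ramp_window("hypovolemic")
  short <- as_observable_series(obs[obs$t < 300, ], fs = 10)
  cfg <- cost_config(n_starts = 2, maxit = 200)
  est <- estimate_trace(short, neonate_meta(), cfg, seed = 2)
  expect_equal(nrow(est$segments), 1)
  expect_equal(est$smoothed$i_ex_rel, est$segments$i_ex_rel)
  ## every estimate within the (tightened) bounds
  for (p in cvstate:::PARAM_NAMES) {
    expect_true(all(est$segments[[p]] >= est$bounds[p, "lo"] - 1e-9))
    expect_true(all(est$segments[[p]] <= est$bounds[p, "hi"] + 1e-9))
  }
  ## an all-invalid record yields an empty trace with a warning
  bad <- const_obs(400, p_p = 5)
  expect_warning(empty <- estimate_trace(bad, neonate_meta(), cfg), "no valid")
  expect_null(empty$segments)
})

test_that("shock indices convert units and locate the segment midpoint", {
  seg <- data.frame(start = c(0, 100), i_ex_rel = c(-0.05, 0),
                    d_v_v0_rel = c(144, 144), m_const = c(-0.3, 0.1),
                    m_slope = c(0, 0), k_max_rel = c(800, 900))
  ix <- shock_indices(seg)
  expect_equal(ix$per_segment$i_bar_ex[1], 60 * -0.05 / 144,
               tolerance = 1e-12)  # about -0.0208 per minute
  expect_equal(ix$per_segment$i_bar_ex[2], 0)
  expect_equal(ix$per_segment$m_svr, c(-0.3, 0.1))
  expect_equal(ix$summary$k_max_rel, 850)
  expect_equal(ix$summary$m_svr_se, sd(c(-0.3, 0.1)) / sqrt(2))
})

test_that("reconstruction is exact at the generating parameters", {
  obs <- ramp_window("distributive")
  seg <- obs[obs$t < 300, ]
  th <- as_scaled_params(neonate_params(), i_ex = 0, s_const = 0.2,
                         m_const = -1 / 6, m_slope = -0.5 / 900,
                         alpha_rc = 1)
  rc <- reconstruct_observables(th, seg)
  expect_equal(unname(rc$correlations), c(1, 1, 1), tolerance = 1e-6)
  expect_equal(rc$reconstruction$hr_bar, seg$hr, tolerance = 1e-6)

  ## constant channels yield flagged NA correlations
  flat <- const_obs(100)
  rc2 <- reconstruct_observables(th, flat)
  expect_true(all(is.na(rc2$correlations)))
  expect_true(all(rc2$constant_channel))

  ## correlating the reconstruction against time-shuffled observations
  ## destroys the agreement (permutation sanity check)
  set.seed(9)
  expect_lt(abs(cor(rc$reconstruction$hr_bar, sample(seg$hr))), 0.2)
})
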