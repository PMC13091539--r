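test_that("capacitance jump: flat trace gives 0, noiseless jump is recovered", {
  flat <- simulate_cm_recording(cm_truth(jump_fF = 0, decay_model = "none"))
  expect_equal(measure_delta_cm_peak(flat), 0, tolerance = 1e-9)

  # Decay correction: back-extrapolated peak within 2% of truth for tau >= 5.
  for (tau in c(5, 10.2, 20)) {
    rec <- simulate_cm_recording(
      cm_truth(jump_fF = 100, decay_model = "mono", tau_s = tau))
    expect_equal(measure_delta_cm_peak(rec), 100, tolerance = 0.02)
  }
  # The plain window mean is the biased alternative, by construction.
  rec5 <- simulate_cm_recording(
    cm_truth(jump_fF = 100, decay_model = "mono", tau_s = 5))
  wm <- measure_delta_cm_peak(rec5, method = "window_mean")
  expect_lt(wm, 100)
  expect_equal(wm, 100 * mean(exp(-seq(0.25, 0.4975, 0.01) / 5)),
               tolerance = 1e-3)
})

test_that("capacitance jump errors when post-stimulus data are unusable", {
  rec <- simulate_cm_recording(cm_truth(jump_fF = 100, decay_model = "none"))
  rec$masked[rec$time_s >= attr(rec, "stim_end_s")] <- TRUE
  expect_error(measure_delta_cm_peak(rec),
               class = "endokin_insufficient_data")
})

test_that("mono fit recovers noiseless parameters to machine precision", {
  rec <- simulate_cm_recording(
    cm_truth(jump_fF = 1, decay_model = "mono", tau_s = 5, baseline_fF = 0))
  fit <- fit_cm_decay(rec, "mono")
  expect_true(fit$converged)
  expect_equal(fit$tau_s, 5, tolerance = 1e-6)
  expect_equal(fit$amplitude_fF, 1, tolerance = 1e-6)
  td <- tidy(fit)
  expect_setequal(td$term, c("plateau", "A", "tau"))
  gl <- glance(fit)
  expect_identical(gl$model, "mono")
})

test_that("bi fit recovers the control bi-exponential decay exactly", {
  rec <- simulate_cm_recording(ctrl_bi_truth(), cm_protocol("depol_20msX10"))
  fit <- fit_cm_decay(rec, "bi")
  expect_true(fit$converged)
  expect_equal(fit$tau1_s, 1.6, tolerance = 1e-4)
  expect_equal(fit$tau2_s, 15.5, tolerance = 1e-4)
  expect_equal(fit$weight1, 0.31, tolerance = 1e-4)
  expect_lt(fit$tau1_s, fit$tau2_s)
})

test_that("pure noise yields an unfit or flagged-uncertain decay", {
  rec <- simulate_cm_recording(
    cm_truth(jump_fF = 0, decay_model = "none", noise_sd_fF = 10, seed = 5))
  fit <- fit_cm_decay(rec, "mono")
  expect_true(!fit$converged || fit$tau_uncertain)
})

test_that("rate of decay: constants, exact linear slopes, analytic value", {
  flat <- simulate_cm_recording(cm_truth(jump_fF = 100, decay_model = "none"))
  expect_equal(compute_rate_decay(flat), 0, tolerance = 1e-9)

  # Exact linear decay at 10 fF/s built directly on the trace.
  lin <- simulate_cm_recording(cm_truth(jump_fF = 100, decay_model = "none"))
  post <- lin$time_s >= attr(lin, "stim_end_s")
  lin$cm_fF[post] <- 5100 - 10 * (lin$time_s[post] - attr(lin, "stim_end_s"))
  expect_equal(compute_rate_decay(lin), 10, tolerance = 1e-9)

  # Mono tau = 10.2 over the single-pulse window: near the analytic LS slope
  # of 100 * exp(-t/10.2) over [0.5, 4] s (~7.89 fF/s).
  rec <- simulate_cm_recording(
    cm_truth(jump_fF = 100, decay_model = "mono", tau_s = 10.2))
  expect_equal(compute_rate_decay(rec), 7.8865, tolerance = 0.01)

  # Window outside the record errors.
  expect_error(compute_rate_decay(rec, window = c(0.5, 1000)),
               class = "endokin_insufficient_data")
})

test_that("rate of decay matches a brute-force regression oracle to 1e-9", {
  for (spec in list(list(p = "depol_20ms", w = c(0.5, 4)),
                    list(p = "depol_20msX10", w = c(0.5, 1.5)))) {
    prot <- cm_protocol(spec$p)
    rec <- simulate_cm_recording(ctrl_mono_truth(), prot)
    stim_end <- attr(rec, "stim_end_s")
    sel <- rec$time_s >= stim_end + spec$w[1] &
      rec$time_s <= stim_end + spec$w[2] & !rec$masked
    oracle <- -brute_slope(rec$time_s[sel], rec$cm_fF[sel])
    expect_equal(compute_rate_decay(rec), oracle, tolerance = 1e-9)
  }
})

test_that("normalized decay rate and the first-second retrieval identity", {
  expect_equal(compute_rate_decay_n(10, 100), 0.1)
  expect_warning(out <- compute_rate_decay_n(10, 0))
  expect_true(is.na(out))
  expect_equal(first_second_retrieval(10.2), 0.0933867, tolerance = 1e-4)
})

test_that("scaling a trace scales the rate but not normalized quantities", {
  truth <- ctrl_mono_truth()
  rec <- simulate_cm_recording(truth)
  for (c_scale in c(0.5, 3)) {
    rec2 <- rec
    rec2$cm_fF <- 5000 + c_scale * (rec$cm_fF - 5000)
    expect_equal(compute_rate_decay(rec2), c_scale * compute_rate_decay(rec),
                 tolerance = 1e-9)
    expect_equal(
      compute_rate_decay(rec2) / measure_delta_cm_peak(rec2),
      compute_rate_decay(rec) / measure_delta_cm_peak(rec),
      tolerance = 1e-9
    )
    expect_equal(fit_cm_decay(rec2)$tau_s, fit_cm_decay(rec)$tau_s,
                 tolerance = 1e-6)
    expect_equal(measure_total_decay_fraction(rec2),
                 measure_total_decay_fraction(rec), tolerance = 1e-9)
  }
})

test_that("endocytic-mode classifier partitions its domain with the stated boundaries", {
  # Every (decay fraction, tau) combination maps to exactly one mode.
  fracs <- c(0.1, 0.29, 0.3, 0.31, 0.8, 1.29, 1.3, 1.31, 1.5)
  taus <- c(0.1, 0.59, 0.6, 0.61, 3, 5.99, 6, 6.01, 20, NA)
  grid <- expand.grid(frac = fracs, tau = taus)
  modes <- classify_endocytic_mode(grid$frac, grid$tau)
  expect_false(any(is.na(modes)))
  expect_equal(length(modes), nrow(grid))

  # Amplitude classes take precedence over the time constant.
  expect_equal(as.character(classify_endocytic_mode(1.4, 3)), "overshoot")
  expect_equal(as.character(classify_endocytic_mode(0.2, 3)), "no_endo")
  # Printed examples and boundary conventions.
  expect_equal(as.character(classify_endocytic_mode(0.8, 0.5)), "ultrafast")
  expect_equal(as.character(classify_endocytic_mode(0.8, 3)), "fast")
  expect_equal(as.character(classify_endocytic_mode(0.8, 10)), "slow")
  expect_equal(as.character(classify_endocytic_mode(0.8, 0.6)), "fast")
  expect_equal(as.character(classify_endocytic_mode(0.8, 6)), "fast")
  # Exactly 30% / 130% fall to the tau-based classes.
  expect_equal(as.character(classify_endocytic_mode(0.3, 10)), "slow")
  expect_equal(as.character(classify_endocytic_mode(1.3, 10)), "slow")
  # No usable tau and intermediate decay: unclassified, not an error.
  expect_equal(as.character(classify_endocytic_mode(0.8, NA)), "unclassified")
})

test_that("calcium-current peak measurement and binning", {
  prot <- cm_protocol("depol_1s")
  mk <- function(peak) simulate_cm_recording(
    cm_truth(jump_fF = 100, decay_model = "none", ica_peak_pA = peak), prot)
  expect_equal(measure_ica(mk(500))$ica_bin, "mid")
  expect_equal(measure_ica(mk(200))$ica_bin, "low")
  expect_equal(measure_ica(mk(1500))$ica_bin, "high")
  # Gap between the printed bins.
  expect_equal(measure_ica(mk(380))$ica_bin, "out_of_bin")
  z <- measure_ica(mk(0))
  expect_equal(z$ica_peak_pA, 0)
  expect_equal(z$ica_bin, "out_of_bin")
  # Missing channel flagged absent.
  rec <- mk(500); rec$ica_pA <- NA_real_
  expect_equal(measure_ica(rec)$ica_bin, "absent")
})

test_that("tau is recovered from noisy mono traces (median error <= 5%)", {
  recs <- simulate_cm_cohort(
    100, ctrl_mono_truth(noise_sd_fF = 10), seed = 1000)
  taus <- vapply(recs, function(r) fit_cm_decay(r)$tau_s, numeric(1))
  expect_lte(median(abs(taus - 10.2)) / 10.2, 0.05)
})

test_that("analyze_cm assembles a consistent one-row kinetics record", {
  rec <- simulate_cm_recording(ctrl_mono_truth(noise_sd_fF = 5, seed = 2))
  kin <- analyze_cm(rec)
  expect_equal(nrow(kin), 1)
  expect_equal(kin$fit_model, "mono")
  expect_equal(kin$rate_decay_n_per_s,
               kin$rate_decay_fF_per_s / kin$delta_cm_peak_fF)
  expect_equal(kin$mode, "slow")
  expect_equal(kin$ica_bin, "high")
  # Train protocol picks the bi model automatically.
  recb <- simulate_cm_recording(ctrl_bi_truth(noise_sd_fF = 5, seed = 2),
                                cm_protocol("depol_20msX10"))
  expect_equal(analyze_cm(recb)$fit_model, "bi")
})
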