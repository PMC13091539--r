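test_that("baseline normalization rescales any raw scale to 100%", {
  tm <- seq(0, 30, 0.1)
  mk <- function(id, base) tibble::tibble(
    bouton_id = id, time_s = tm,
    f_raw = base * (1 + 0.5 * (tm >= 10)))
  boutons <- dplyr::bind_rows(mk("b1", 50), mk("b2", 200))
  exp_trace <- normalize_and_average(boutons, onset_s = 10, stim_end_s = 20)
  expect_equal(exp_trace$f_percent[exp_trace$time_s < 10],
               rep(100, sum(tm < 10)), tolerance = 1e-9)
  expect_equal(exp_trace$f_percent[exp_trace$time_s >= 10],
               rep(150, sum(tm >= 10)), tolerance = 1e-9)
  # A single bouton already at 100% baseline passes through unchanged.
  one <- tibble::tibble(bouton_id = "b", time_s = tm,
                        f_percent = 100 + 50 * (tm >= 10))
  expect_equal(normalize_and_average(one, 10, 20)$f_percent, one$f_percent,
               tolerance = 1e-9)
  # No baseline frames is an error.
  late <- tibble::tibble(bouton_id = "b", time_s = tm + 50, f_percent = 100)
  expect_error(normalize_and_average(late, 10, 20),
               class = "endokin_insufficient_data")
})

test_that("noiseless peak and decay-rate estimates equal the generator truth", {
  b <- simulate_syph_experiment(peak_dff = 161, n_boutons = 20,
                                noise_sd = 0, bouton_cv = 0)
  exp_trace <- normalize_and_average(b)
  expect_equal(compute_dff_peak(exp_trace), 161, tolerance = 1e-9)
  # Constant-rate decay losing 3.9% of the rise per second.
  expect_equal(compute_syph_rate_decay_n(exp_trace), 3.9, tolerance = 1e-9)

  # Flat trace: zero peak, undefined rate.
  flat <- tibble::tibble(bouton_id = "b", time_s = seq(0, 60, 0.1),
                         f_percent = 100)
  ft <- normalize_and_average(flat, onset_s = 10, stim_end_s = 20)
  expect_equal(compute_dff_peak(ft), 0, tolerance = 1e-9)
  expect_warning(r <- compute_syph_rate_decay_n(ft))
  expect_true(is.na(r))

  # Constant post-peak trace has zero decay rate.
  const <- simulate_syph_experiment(
    peak_dff = 50, decay = list(type = "constant_rate", rate_pct_per_s = 0),
    n_boutons = 3, noise_sd = 0, bouton_cv = 0)
  expect_equal(compute_syph_rate_decay_n(normalize_and_average(const)), 0,
               tolerance = 1e-9)
})

test_that("mono-exponential decay matches the analytic LS slope oracle", {
  tau <- 20
  b <- simulate_syph_experiment(peak_dff = 100,
                                decay = list(type = "mono", tau_s = tau),
                                n_boutons = 5, noise_sd = 0, bouton_cv = 0)
  exp_trace <- normalize_and_average(b)
  # Oracle: brute-force slope over the same frames used by the estimator.
  t_peak <- 20
  win <- exp_trace$time_s >= t_peak & exp_trace$time_s <= t_peak + 6
  oracle <- -brute_slope(exp_trace$time_s[win], exp_trace$f_percent[win]) / 100 * 100
  expect_equal(compute_syph_rate_decay_n(exp_trace), oracle, tolerance = 1e-9)
  # And the mono fit recovers the generating time constant.
  expect_equal(fit_syph_decay(exp_trace)$tau_s, tau, tolerance = 1e-3)
})

test_that("decay rate is invariant to rescaling the rise above baseline", {
  b <- simulate_syph_experiment(peak_dff = 161, n_boutons = 10,
                                noise_sd = 0, bouton_cv = 0)
  exp_trace <- normalize_and_average(b)
  r1 <- compute_syph_rate_decay_n(exp_trace)
  scaled <- exp_trace
  scaled$f_percent <- 100 + 2.5 * (exp_trace$f_percent - 100)
  expect_equal(compute_syph_rate_decay_n(scaled), r1, tolerance = 1e-9)
})

test_that("noisy peak estimate carries only the documented positive bias", {
  # Max-over-frames statistic: bias positive and bounded by ~2 SD of the
  # experiment-average frame noise.
  est <- vapply(1:10, function(i) {
    b <- simulate_syph_experiment(peak_dff = 100, n_boutons = 20,
                                  noise_sd = 5, bouton_cv = 0, seed = 40 + i)
    compute_dff_peak(normalize_and_average(b))
  }, numeric(1))
  sigma_avg <- 5 / sqrt(20)
  expect_gte(mean(est), 100 - 0.5 * sigma_avg)
  expect_lte(mean(est) - 100, 2 * sigma_avg)
})

test_that("constant-rate decay is recovered across seeded experiments", {
  rate <- 3.9
  est <- vapply(1:20, function(i) {
    b <- simulate_syph_experiment(seed = 700 + i)
    compute_syph_rate_decay_n(normalize_and_average(b))
  }, numeric(1))
  sem <- sd(est) / sqrt(length(est))
  sigma_avg <- 3 / sqrt(20)
  # Mean within 2 s.e.m. plus the peak-bias propagation bound.
  expect_lt(abs(mean(est) - rate), 2 * sem + rate * 2 * sigma_avg / 161)
})

test_that("invalid pHluorin configurations are rejected", {
  expect_error(simulate_syph_experiment(peak_dff = -5),
               class = "endokin_invalid_config")
  expect_error(simulate_syph_experiment(n_boutons = 0),
               class = "endokin_invalid_config")
  b <- simulate_syph_experiment(seed = 1)
  expect_error(compute_syph_rate_decay_n(normalize_and_average(b), window_s = 20),
               class = "endokin_invalid_config")
})
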