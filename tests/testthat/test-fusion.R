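test_that("fusion onset is found on canonical traces and rejected on artifacts", {
  tr <- simulate_spot_trace(spot_truth("close_fusion", onset_s = 5))
  expect_equal(detect_fusion_onset(tr), 5, tolerance = 0.05 + 1e-9)

  # Flat trace: nothing to detect.
  expect_true(is.na(detect_fusion_onset(flat_spot_trace())))

  # Membrane-label rise alone (no dye, no content release) is rejected.
  tr2 <- flat_spot_trace()
  tr2$f_ffn <- 100
  tr2$f_ph[tr2$time_s >= 5] <- 120
  tr2$f_655 <- 20
  expect_true(is.na(detect_fusion_onset(tr2)))

  # Too little baseline is an error.
  short <- dplyr::filter(tr, time_s >= 34.5)
  expect_error(detect_fusion_onset(short),
               class = "endokin_insufficient_data")
})

test_that("noiseless canonical traces are classified as generated", {
  for (m in c("close_fusion", "stay_fusion", "shrink_fusion")) {
    tr <- simulate_spot_trace(spot_truth(m))
    ev <- classify_fusion_mode(tr, detect_fusion_onset(tr))
    expect_equal(ev$mode, m)
  }
  # Close-fusion closure time: truth + bleach-dependent half-dimming offset.
  tr <- simulate_spot_trace(spot_truth("close_fusion", closure_time_s = 2,
                                       a655_bleach_tau_s = 0.3))
  ev <- classify_fusion_mode(tr, detect_fusion_onset(tr))
  expect_equal(ev$closure_time_s, 2 + 0.3 * log(2), tolerance = 0.1)

  # Stay-fusion censoring depends on the observation span after onset.
  short <- simulate_spot_trace(spot_truth("stay_fusion", record_s = 20))
  expect_true(classify_fusion_mode(short, detect_fusion_onset(short))$censored)
  long <- simulate_spot_trace(spot_truth("stay_fusion", record_s = 36))
  expect_false(classify_fusion_mode(long, detect_fusion_onset(long))$censored)

  # Shrink: channels decline in parallel and the spot size shrinks.
  trs <- simulate_spot_trace(spot_truth("shrink_fusion"))
  post <- trs$time_s >= 5.5 & trs$time_s <= 15
  expect_gte(cor(trs$f_ph[post], trs$f_655[post]), 0.99)
  expect_true(all(diff(trs$size_nm[trs$time_s >= 5.5]) <= 1e-9))
})

test_that("pre-existing spot pore closure is detected and parallel loss is not", {
  expect_true(detect_pre_close(simulate_spot_trace(spot_truth("pre_close"))))
  expect_false(detect_pre_close(simulate_spot_trace(spot_truth("no_close"))))
  # Both channels decaying together is a parallel loss, not pore closure.
  par <- simulate_spot_trace(spot_truth("no_close"))
  dec <- exp(-pmax(0, par$time_s - 6) / 2)
  par$f_ph <- 20 + 100 * dec
  par$f_655 <- 20 + 100 * dec
  expect_false(detect_pre_close(par))
})

test_that("release time: linear ramp, exponential closed form, censoring", {
  # Linear 100 -> 0 over 10 s: the 20-80% decay time is 6 s exactly.
  tm <- seq(0, 30, 0.05)
  lin <- tibble::tibble(
    cell_id = "c", spot_id = "s", spot_kind = "fusion_candidate",
    time_s = tm, f_ph = 20, f_655 = 20,
    f_ffn = pmax(0, 100 * (1 - pmax(0, tm - 5) / 10)), size_nm = NA_real_)
  out <- compute_t_ffn(lin, 5)
  expect_false(out$censored)
  expect_equal(out$t_ffn_s, 6, tolerance = 1e-9)

  # Exponential release: T = tau * ln 4, within one frame across taus.
  for (tau in c(0.5, 1, 2, 5, 10)) {
    tr <- simulate_spot_trace(spot_truth("stay_fusion",
                                         ffn_release_tau_s = tau,
                                         record_s = 85))
    out <- compute_t_ffn(tr, 5)
    expect_false(out$censored)
    expect_lt(abs(out$t_ffn_s - tau * log(4)), 0.05)
  }

  # Constant content channel: censored, no value.
  const <- lin
  const$f_ffn <- 100
  out <- compute_t_ffn(const, 5)
  expect_true(out$censored)
  expect_true(is.na(out$t_ffn_s))

  # Decay still in progress at record end: censored.
  slow <- simulate_spot_trace(spot_truth("stay_fusion",
                                         ffn_release_tau_s = 30,
                                         record_s = 20))
  expect_true(compute_t_ffn(slow, 5)$censored)
})

test_that("confusion matrix on noiseless canonical traces is the identity", {
  modes <- c("close_fusion", "stay_fusion", "shrink_fusion")
  got <- vapply(modes, function(m) {
    tr <- simulate_spot_trace(spot_truth(m))
    classify_fusion_mode(tr, detect_fusion_onset(tr))$mode
  }, character(1))
  expect_identical(unname(got), modes)
  expect_true(detect_pre_close(simulate_spot_trace(spot_truth("pre_close"))))
  expect_false(detect_pre_close(simulate_spot_trace(spot_truth("no_close"))))
})

test_that("per-cell summaries apply the exclusion rule and conserve counts", {
  ev <- tibble::tibble(
    cell_id = c(rep("c1", 10), rep("c2", 4)),
    spot_id = paste0("s", 1:14),
    onset_s = 5,
    mode = c(rep("close_fusion", 4), rep("stay_fusion", 4),
             rep("shrink_fusion", 2), rep("close_fusion", 2),
             rep("stay_fusion", 2)),
    closure_time_s = NA_real_, censored = FALSE,
    t_ffn_s = c(rep(2, 10), rep(3, 4)), t_ffn_censored = FALSE)
  pre <- tibble::tibble(cell_id = c("c1", "c1"), spot_id = c("p1", "p2"),
                        closed = c(TRUE, FALSE))
  cells <- summarize_fusion_cells(ev, pre)

  c1 <- cells[cells$cell_id == "c1", ]
  expect_equal(c1$n_fusion_events, 10)
  expect_equal(c1$prob_close_fusion, 0.4)
  expect_equal(c1$n_close + c1$n_stay + c1$n_shrink + c1$n_ambiguous,
               c1$n_fusion_events)
  expect_false(c1$excluded)
  expect_equal(c1$prob_pre_close, 0.5)

  # Fewer than five events: excluded, retained with a flag.
  c2 <- cells[cells$cell_id == "c2", ]
  expect_true(c2$excluded)
  expect_equal(c2$n_fusion_events, 4)
  # No pre-existing spots: probability undefined.
  expect_true(is.na(c2$prob_pre_close))

  # Permutation invariance of the event order.
  perm <- ev[sample(nrow(ev)), ]
  cells_perm <- summarize_fusion_cells(perm, pre)
  expect_equal(dplyr::arrange(cells_perm, cell_id),
               dplyr::arrange(cells, cell_id))

  # Censored release times are excluded from the cell mean.
  ev$t_ffn_censored[1:5] <- TRUE
  cells2 <- summarize_fusion_cells(ev, pre)
  expect_equal(cells2$mean_t_ffn_s[cells2$cell_id == "c1"], 2)
})

test_that("the classify table driver handles mixed spot kinds end to end", {
  spots <- dplyr::bind_rows(
    simulate_spot_trace(spot_truth("close_fusion", noise_sd = 5, seed = 1),
                        spot_id = "s1", cell_id = "c1"),
    simulate_spot_trace(spot_truth("stay_fusion", noise_sd = 5, seed = 2),
                        spot_id = "s2", cell_id = "c1"),
    simulate_spot_trace(spot_truth("pre_close", noise_sd = 5, seed = 3),
                        spot_id = "p1", cell_id = "c1"),
    flat_spot_trace() |> dplyr::mutate(spot_id = "s3", cell_id = "c1",
                                       spot_kind = "fusion_candidate")
  )
  res <- classify_fusion_table(spots)
  expect_equal(nrow(res$events), 2)  # the flat spot never fused
  expect_setequal(res$events$mode, c("close_fusion", "stay_fusion"))
  expect_equal(nrow(res$pre_spots), 1)
  expect_true(res$pre_spots$closed)
})

test_that("spot-truth validation enforces the physical ranges", {
  expect_error(spot_truth("close_fusion", closure_time_s = 40),
               class = "endokin_invalid_config")
  expect_error(spot_truth("close_fusion", frame_interval_s = 0.02),
               class = "endokin_invalid_config")
  expect_error(spot_truth("close_fusion", noise_sd = -1),
               class = "endokin_invalid_config")
})
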