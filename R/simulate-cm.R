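#' Ground truth for a simulated capacitance recording
#'
#' Bundles the generating parameters of one synthetic whole-cell capacitance
#' trace: the capacitance jump evoked by the stimulus, the recovery (decay)
#' model that emulates endocytosis, and the sampling/noise regime. Decay
#' models: `"mono"` (single exponential back to baseline), `"bi"` (sum of a
#' rapid and a slow exponential), `"none"` (no recovery), and `"overshoot"`
#' (mono-exponential recovery past baseline so that total retrieval exceeds
#' the jump by `overshoot_fraction`).
#'
#' @param jump_fF Capacitance jump at stimulus end (fF).
#' @param decay_model One of `"mono"`, `"bi"`, `"none"`, `"overshoot"`.
#' @param tau_s Time constant for `"mono"`/`"overshoot"` (s).
#' @param tau1_s,tau2_s,weight1 Rapid and slow time constants and the rapid
#'   amplitude fraction (in (0, 1)) for `"bi"`; the fitted counterpart of
#'   `weight1` is the rapid-component amplitude share.
#' @param overshoot_fraction Total decay as a fraction of the jump for
#'   `"overshoot"` (> 1; e.g. 1.4 means 140% of the jump is retrieved).
#' @param baseline_fF Pre-stimulus membrane capacitance (fF).
#' @param noise_sd_fF SD of additive Gaussian sampling noise (fF).
#' @param ica_peak_pA Peak inward calcium current during each pulse (pA,
#'   magnitude; the trace stores inward current as negative).
#' @param sample_rate_hz Sampling rate of the emitted trace (Hz).
#' @param pre_stim_s Baseline span recorded before stimulus onset (s).
#' @param record_length_s Trace length after stimulus end (s).
#' @param seed Optional integer seed making the trace reproducible.
#'
#' @return An object of class `cm_truth` (a validated list).
#' @export
cm_truth <- function(jump_fF,
                     decay_model = c("mono", "bi", "none", "overshoot"),
                     tau_s = NULL,
                     tau1_s = NULL, tau2_s = NULL, weight1 = NULL,
                     overshoot_fraction = NULL,
                     baseline_fF = 5000,
                     noise_sd_fF = 0,
                     ica_peak_pA = 1200,
                     sample_rate_hz = 100,
                     pre_stim_s = 2,
                     record_length_s = 60,
                     seed = NULL) {
  decay_model <- match.arg(decay_model)
  if (sample_rate_hz <= 0) stop_invalid("`sample_rate_hz` must be > 0.")
  if (record_length_s <= 0) stop_invalid("`record_length_s` must be > 0.")
  if (pre_stim_s <= 0) stop_invalid("`pre_stim_s` must be > 0.")
  if (noise_sd_fF < 0) stop_invalid("`noise_sd_fF` must be >= 0.")
  if (decay_model %in% c("mono", "overshoot")) {
    if (is.null(tau_s) || tau_s <= 0) stop_invalid("`tau_s` must be > 0.")
  }
  if (decay_model == "bi") {
    if (is.null(tau1_s) || is.null(tau2_s) || tau1_s <= 0 || tau2_s <= 0) {
      stop_invalid("`tau1_s` and `tau2_s` must be > 0 for a bi-exponential decay.")
    }
    if (is.null(weight1) || weight1 <= 0 || weight1 >= 1) {
      stop_invalid("`weight1` must lie in (0, 1).")
    }
  }
  if (decay_model == "overshoot") {
    if (is.null(overshoot_fraction) || overshoot_fraction <= 1) {
      stop_invalid("`overshoot_fraction` must exceed 1 (decay beyond baseline).")
    }
  }
  structure(
    list(
      jump_fF = jump_fF, decay_model = decay_model,
      tau_s = tau_s, tau1_s = tau1_s, tau2_s = tau2_s, weight1 = weight1,
      overshoot_fraction = overshoot_fraction,
      baseline_fF = baseline_fF, noise_sd_fF = noise_sd_fF,
      ica_peak_pA = ica_peak_pA, sample_rate_hz = sample_rate_hz,
      pre_stim_s = pre_stim_s, record_length_s = record_length_s,
      seed = seed
    ),
    class = "cm_truth"
  )
}

# Noiseless capacitance deviation from baseline at time t' after stimulus
# end, per the truth's decay model. Exposed internally for closed-form tests.
cm_decay_curve <- function(truth, t_post) {
  dev <- numeric(length(t_post))
  post <- t_post >= 0
  tp <- t_post[post]
  dev[post] <- switch(truth$decay_model,
    none = truth$jump_fF,
    mono = truth$jump_fF * exp(-tp / truth$tau_s),
    bi = truth$jump_fF * (truth$weight1 * exp(-tp / truth$tau1_s) +
                            (1 - truth$weight1) * exp(-tp / truth$tau2_s)),
    overshoot = truth$jump_fF *
      (1 - truth$overshoot_fraction * (1 - exp(-tp / truth$tau_s)))
  )
  dev
}

#' Simulate a stimulus-locked capacitance recording
#'
#' Generates one synthetic whole-cell capacitance trace with a paired
#' calcium-current trace. The trace sits at baseline before the stimulus,
#' jumps by `jump_fF` instantaneously at stimulus end (intra-train
#' exocytosis kinetics are not modeled), and then recovers according to the
#' truth's decay model. Samples in the `artifact_blank_s` window after
#' stimulus end are emitted but flagged `masked = TRUE`; the analyzers, not
#' the simulator, own the exclusion rule. Time zero is stimulus onset.
#'
#' @param truth A [cm_truth()] object.
#' @param protocol A [cm_protocol()] object.
#' @param recording_id,cell_id,condition Identifier strings carried through
#'   to the output.
#'
#' @return A tibble of class `cm_recording` with columns `time_s`, `cm_fF`,
#'   `ica_pA`, `masked`, and attributes `protocol`, `truth`, `onset_s` (0)
#'   and `stim_end_s`.
#' @examples
#' rec <- simulate_cm_recording(
#'   cm_truth(jump_fF = 531, decay_model = "mono", tau_s = 10.2,
#'            noise_sd_fF = 10, seed = 1),
#'   cm_protocol("depol_20ms")
#' )
#' measure_delta_cm_peak(rec)
#' @export
simulate_cm_recording <- function(truth, protocol = cm_protocol("depol_20ms"),
                                  recording_id = "rec1", cell_id = recording_id,
                                  condition = "control") {
  stopifnot(inherits(truth, "cm_truth"), inherits(protocol, "cm_protocol"))
  dt <- 1 / truth$sample_rate_hz
  stim_end <- protocol$stim_duration_s
  time_s <- seq(-truth$pre_stim_s, stim_end + truth$record_length_s, by = dt)
  t_post <- time_s - stim_end

  cm <- truth$baseline_fF + cm_decay_curve(truth, t_post)
  # Artifact window: [stim_end, stim_end + blank), so the first clean sample
  # falls exactly at stim_end + blank when it lies on the sampling grid
  # (tolerance guards against floating-point grid fuzz).
  masked <- t_post >= -1e-9 & t_post < protocol$artifact_blank_s - 1e-9

  ica <- numeric(length(time_s))
  pulse_starts <- (seq_len(protocol$n_pulses) - 1L) / protocol$pulse_rate_hz
  for (ps in pulse_starts) {
    ica[time_s >= ps & time_s < ps + protocol$pulse_duration_s] <- -truth$ica_peak_pA
  }

  if (truth$noise_sd_fF > 0) {
    cm <- cm + with_seed_if(truth$seed, rnorm(length(cm), 0, truth$noise_sd_fF))
  }

  out <- tibble(
    recording_id = recording_id,
    time_s = time_s,
    cm_fF = cm,
    ica_pA = ica,
    masked = masked
  )
  structure(
    out,
    protocol = protocol,
    truth = truth,
    onset_s = 0,
    stim_end_s = stim_end,
    cell_id = cell_id,
    condition = condition,
    class = c("cm_recording", class(out))
  )
}

#' Simulate a cohort of capacitance recordings
#'
#' Convenience wrapper generating `n` recordings that share one ground truth
#' but receive independent noise, with per-trace seeds derived as
#' `seed + i - 1` so individual traces can be regenerated in isolation.
#'
#' @param n Number of recordings.
#' @param truth,protocol As in [simulate_cm_recording()].
#' @param seed Base integer seed (the i-th trace uses `seed + i - 1`).
#' @param condition Condition label shared by the cohort.
#' @return A list of `cm_recording` tibbles.
#' @export
simulate_cm_cohort <- function(n, truth, protocol = cm_protocol("depol_20ms"),
                               seed = 1, condition = "control") {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    truth_i <- truth
    truth_i$seed <- seed + i - 1
    simulate_cm_recording(truth_i, protocol,
                          recording_id = sprintf("%s_%02d", condition, i),
                          condition = condition)
  })
}

#' Write / read a capacitance recording as long-format CSV
#'
#' The on-disk form is one row per (channel, sample):
#' `recording_id, channel, time_s, value, masked`, with a JSON sidecar
#' (`<path>.json`) carrying the protocol and, when the recording was
#' simulated, its ground truth.
#'
#' @param rec A `cm_recording`.
#' @param path CSV file path.
#' @return `write_cm_recording()` returns `path` invisibly;
#'   `read_cm_recording()` returns a `cm_recording` tibble.
#' @export
write_cm_recording <- function(rec, path) {
  long <- dplyr::bind_rows(
    tibble(recording_id = rec$recording_id, channel = "cm_fF",
           time_s = rec$time_s, value = rec$cm_fF, masked = rec$masked),
    tibble(recording_id = rec$recording_id, channel = "ica_pA",
           time_s = rec$time_s, value = rec$ica_pA, masked = rec$masked)
  )
  readr::write_csv(long, path)
  sidecar <- list(
    protocol = unclass(attr(rec, "protocol")),
    truth = if (!is.null(attr(rec, "truth"))) unclass(attr(rec, "truth")),
    onset_s = attr(rec, "onset_s"),
    cell_id = attr(rec, "cell_id"),
    condition = attr(rec, "condition")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_cm_recording
#' @export
read_cm_recording <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  p <- side$protocol
  protocol <- cm_protocol(p$name, pulse_duration_s = p$pulse_duration_s,
                          n_pulses = p$n_pulses, pulse_rate_hz = p$pulse_rate_hz,
                          holding_mV = p$holding_mV, step_mV = p$step_mV,
                          artifact_blank_s = p$artifact_blank_s)
  wide <- long |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value") |>
    dplyr::arrange(.data$time_s)
  out <- tibble(
    recording_id = wide$recording_id,
    time_s = wide$time_s,
    cm_fF = wide$cm_fF,
    ica_pA = wide$ica_pA,
    masked = wide$masked
  )
  structure(
    out,
    protocol = protocol,
    onset_s = side$onset_s %||% 0,
    stim_end_s = protocol$stim_duration_s,
    cell_id = side$cell_id,
    condition = side$condition,
    class = c("cm_recording", class(out))
  )
}
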