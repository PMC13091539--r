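#' Depolarization protocols for capacitance recordings
#'
#' Describes the voltage-step stimulation used to evoke exo-endocytosis in
#' whole-cell capacitance recordings: a single 20 ms step (`depol_20ms`), a
#' 10 Hz train of ten 20 ms steps (`depol_20msX10`), or a single 1 s step
#' (`depol_1s`), each from a holding potential of -80 mV to +10 mV. The
#' first `artifact_blank` seconds of the capacitance trace after stimulus
#' end are contaminated by the stimulus artifact and are flagged unusable by
#' the simulator and skipped by the analyzers.
#'
#' @param name Protocol name, one of `"depol_20ms"`, `"depol_20msX10"`,
#'   `"depol_1s"`.
#' @param pulse_duration_s Duration of a single depolarizing pulse (s).
#' @param n_pulses Number of pulses (10 for the train, else 1).
#' @param pulse_rate_hz Pulse rate within a train (Hz).
#' @param holding_mV,step_mV Holding and step potentials (mV).
#' @param artifact_blank_s Length of the post-stimulus capacitance artifact
#'   window (s); samples inside it are masked, not dropped.
#'
#' @return An object of class `cm_protocol`: a list with the fields above
#'   plus `stim_duration_s`, the onset-to-end span
#'   `(n_pulses - 1) / pulse_rate_hz + pulse_duration_s`.
#' @examples
#' cm_protocol("depol_20msX10")$stim_duration_s  # 0.92 s
#' @export
cm_protocol <- function(name = c("depol_20ms", "depol_20msX10", "depol_1s"),
                        pulse_duration_s = NULL,
                        n_pulses = NULL,
                        pulse_rate_hz = 10,
                        holding_mV = -80,
                        step_mV = 10,
                        artifact_blank_s = 0.25) {
  name <- match.arg(name)
  defaults <- switch(name,
    depol_20ms    = list(dur = 0.02, n = 1L),
    depol_20msX10 = list(dur = 0.02, n = 10L),
    depol_1s      = list(dur = 1.00, n = 1L)
  )
  pulse_duration_s <- pulse_duration_s %||% defaults$dur
  n_pulses <- as.integer(n_pulses %||% defaults$n)
  if (n_pulses < 1L) stop_invalid("`n_pulses` must be >= 1.")
  if (name == "depol_20msX10" && (n_pulses != 10L || pulse_rate_hz != 10)) {
    stop_invalid("depol_20msX10 is defined as exactly 10 pulses at 10 Hz.")
  }
  if (pulse_duration_s <= 0) stop_invalid("`pulse_duration_s` must be > 0.")
  if (artifact_blank_s < 0) stop_invalid("`artifact_blank_s` must be >= 0.")
  structure(
    list(
      name = name,
      pulse_duration_s = pulse_duration_s,
      n_pulses = n_pulses,
      pulse_rate_hz = pulse_rate_hz,
      holding_mV = holding_mV,
      step_mV = step_mV,
      artifact_blank_s = artifact_blank_s,
      stim_duration_s = (n_pulses - 1L) / pulse_rate_hz + pulse_duration_s
    ),
    class = "cm_protocol"
  )
}

#' @export
print.cm_protocol <- function(x, ...) {
  cat(sprintf(
    "<cm_protocol> %s: %d x %g ms at %g Hz (%g to %g mV), stim span %g s, artifact blank %g s\n",
    x$name, x$n_pulses, 1000 * x$pulse_duration_s, x$pulse_rate_hz,
    x$holding_mV, x$step_mV, x$stim_duration_s, x$artifact_blank_s
  ))
  invisible(x)
}
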