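#' Ground truth for a simulated fusion-spot trace
#'
#' Parameters of one three-channel spot time series from cell-bottom
#' confocal imaging: membrane label (`f_ph`, weak excitation), bath dye
#' trapped in the vesicle lumen (`f_655`, strong excitation, so it bleaches
#' once the pore closes and exchange with the bath stops), vesicular
#' false-transmitter content (`f_ffn`, released on fusion), and spot size
#' (Gaussian FWHM, nm). Modes:
#' \describe{
#'   \item{close_fusion}{fusion at `onset_s`, pore closes `closure_time_s`
#'     later: `f_655` bleaches toward background from closure while `f_ph`
#'     stays high for `ph_delay_s` more before decaying (vesicle pinch-off).}
#'   \item{stay_fusion}{pore stays open: both channels sustained to record
#'     end.}
#'   \item{shrink_fusion}{the fused vesicle shrinks into the membrane:
#'     `f_ph`, `f_655` and spot size decline in parallel.}
#'   \item{pre_close}{a pre-existing spot (no fusion, no `f_ffn`): `f_655`
#'     bleaches after closure while `f_ph` stays constant.}
#'   \item{no_close}{a pre-existing spot whose pore stays open: both
#'     channels constant.}
#' }
#'
#' @param mode One of the five modes above.
#' @param onset_s Fusion (or stimulus) time (s).
#' @param closure_time_s Onset-to-pore-closure interval (s); pore closure
#'   occurs 0.05-30 s after fusion for closing modes.
#' @param ffn_release_tau_s Release (decay) time constant of `f_ffn` (s).
#' @param a655_bleach_tau_s Post-closure bleaching time constant of `f_655`
#'   (s).
#' @param ph_delay_s Lag of the `f_ph` decay behind the `f_655` dimming (s).
#' @param ph_decay_tau_s Time constant of the delayed `f_ph` decay (s).
#' @param shrink_delay_s,shrink_tau_s Start (after onset) and time constant
#'   of the parallel shrink decline (s).
#' @param frame_interval_s Frame interval, within 0.04-0.08 s.
#' @param record_s Record length (s).
#' @param baseline Background fluorescence level (a.u.).
#' @param amplitude Post-onset channel amplitude above background (a.u.).
#' @param size_nm Initial spot FWHM (nm).
#' @param noise_sd Additive Gaussian noise SD on each channel (a.u.; also
#'   applied to size in nm).
#' @param seed Optional integer seed.
#' @return An object of class `spot_truth`.
#' @export
spot_truth <- function(mode = c("close_fusion", "stay_fusion", "shrink_fusion",
                                "pre_close", "no_close"),
                       onset_s = 5,
                       closure_time_s = 2,
                       ffn_release_tau_s = 1.5,
                       a655_bleach_tau_s = 0.3,
                       ph_delay_s = 1.5,
                       ph_decay_tau_s = 2,
                       shrink_delay_s = 0.5,
                       shrink_tau_s = 3,
                       frame_interval_s = 0.05,
                       record_s = 35,
                       baseline = 20,
                       amplitude = 100,
                       size_nm = 400,
                       noise_sd = 0,
                       seed = NULL) {
  mode <- match.arg(mode)
  if (frame_interval_s < 0.04 || frame_interval_s > 0.08) {
    stop_invalid("`frame_interval_s` must lie within [0.04, 0.08] s.")
  }
  if (mode %in% c("close_fusion", "pre_close") &&
      (closure_time_s < 0.05 || closure_time_s > 30)) {
    stop_invalid("`closure_time_s` must lie within [0.05, 30] s for closing modes.")
  }
  if (onset_s < 1) stop_invalid("Need at least 1 s of pre-event baseline.")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0.")
  structure(
    list(mode = mode, onset_s = onset_s, closure_time_s = closure_time_s,
         ffn_release_tau_s = ffn_release_tau_s,
         a655_bleach_tau_s = a655_bleach_tau_s,
         ph_delay_s = ph_delay_s, ph_decay_tau_s = ph_decay_tau_s,
         shrink_delay_s = shrink_delay_s, shrink_tau_s = shrink_tau_s,
         frame_interval_s = frame_interval_s, record_s = record_s,
         baseline = baseline, amplitude = amplitude, size_nm = size_nm,
         noise_sd = noise_sd, seed = seed),
    class = "spot_truth"
  )
}

#' Simulate a three-channel fusion-spot trace
#'
#' Emits the canonical channel kinematics for the truth's mode (see
#' [spot_truth()]): at fusion onset `f_ph` and `f_655` step up together
#' while `f_ffn` starts an exponential release decay; afterwards the
#' channels follow the mode-specific closure/sustain/shrink dynamics.
#' Pre-existing-spot modes carry no `f_ffn` channel (NA).
#'
#' @param truth A `spot_truth`.
#' @param spot_id,cell_id Identifiers carried to the output.
#' @return A tibble of class `spot_trace` with columns `cell_id`,
#'   `spot_id`, `spot_kind` (`"fusion_candidate"` or `"pre_spot"`),
#'   `time_s`, `f_ph`, `f_655`, `f_ffn`, `size_nm` and attribute `truth`.
#' @export
simulate_spot_trace <- function(truth, spot_id = "spot1", cell_id = "cell1") {
  stopifnot(inherits(truth, "spot_truth"))
  tr <- truth
  time_s <- seq(0, tr$record_s, by = tr$frame_interval_s)
  n <- length(time_s)
  base <- tr$baseline
  hi <- tr$baseline + tr$amplitude
  pre_spot <- tr$mode %in% c("pre_close", "no_close")
  spot_kind <- if (pre_spot) "pre_spot" else "fusion_candidate"

  f_ph <- rep(base, n)
  f_655 <- rep(base, n)
  f_ffn <- rep(NA_real_, n)
  size <- rep(tr$size_nm, n)
  post <- time_s >= tr$onset_s
  tp <- time_s[post] - tr$onset_s

  if (pre_spot) {
    # Pre-existing spot: both channels start high; no content channel.
    f_ph <- rep(hi, n)
    f_655 <- rep(hi, n)
    if (tr$mode == "pre_close") {
      td <- tr$onset_s + tr$closure_time_s
      dim_idx <- time_s >= td
      f_655[dim_idx] <- base + tr$amplitude *
        exp(-(time_s[dim_idx] - td) / tr$a655_bleach_tau_s)
    }
  } else {
    f_ph[post] <- hi
    f_655[post] <- hi
    f_ffn <- rep(tr$amplitude, n)
    f_ffn[post] <- tr$amplitude * exp(-tp / tr$ffn_release_tau_s)

    if (tr$mode == "close_fusion") {
      td <- tr$onset_s + tr$closure_time_s
      dim_idx <- time_s >= td
      f_655[dim_idx] <- base + tr$amplitude *
        exp(-(time_s[dim_idx] - td) / tr$a655_bleach_tau_s)
      tph <- td + tr$ph_delay_s
      ph_idx <- time_s >= tph
      f_ph[ph_idx] <- base + tr$amplitude *
        exp(-(time_s[ph_idx] - tph) / tr$ph_decay_tau_s)
    } else if (tr$mode == "shrink_fusion") {
      ts <- tr$onset_s + tr$shrink_delay_s
      sh <- time_s >= ts
      decayf <- exp(-(time_s[sh] - ts) / tr$shrink_tau_s)
      f_ph[sh] <- base + tr$amplitude * decayf
      f_655[sh] <- base + tr$amplitude * decayf
      size[sh] <- tr$size_nm * decayf
    }
  }

  if (tr$noise_sd > 0) {
    noise <- with_seed_if(tr$seed, matrix(rnorm(4L * n, 0, tr$noise_sd), ncol = 4L))
    f_ph <- f_ph + noise[, 1]
    f_655 <- f_655 + noise[, 2]
    if (!pre_spot) f_ffn <- f_ffn + noise[, 3]
    size <- size + noise[, 4]
  }

  out <- tibble(
    cell_id = cell_id, spot_id = spot_id, spot_kind = spot_kind,
    time_s = time_s, f_ph = f_ph, f_655 = f_655, f_ffn = f_ffn,
    size_nm = size
  )
  structure(out, truth = truth, class = c("spot_trace", class(out)))
}
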