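#' Simulate a synapto-pHluorin bouton imaging experiment
#'
#' Generates per-bouton fluorescence traces sampled at 10 Hz, normalized so
#' the pre-stimulus baseline is 100%. An action-potential train (default
#' 20 Hz for 10 s) drives a linear fluorescence rise to `peak_dff` percent
#' above baseline at train end (exocytosis), followed by a decay
#' (endocytosis plus re-acidification) set by `decay`:
#' `list(type = "constant_rate", rate_pct_per_s = r)` loses a constant `r`
#' percent of the peak rise per second until the trace returns to baseline,
#' while `list(type = "mono", tau_s = tau)` decays exponentially. Bouton
#' heterogeneity is modeled as a per-bouton multiplicative peak factor with
#' coefficient of variation `bouton_cv`; frame noise is additive Gaussian.
#'
#' @param peak_dff Mean peak fluorescence rise over baseline (%).
#' @param decay Decay specification (see above).
#' @param n_boutons Number of bouton ROIs (the imaging protocol analyzes
#'   10-30 per experiment).
#' @param noise_sd Per-frame Gaussian noise SD, percent of baseline.
#' @param bouton_cv Coefficient of variation of per-bouton peak amplitudes.
#' @param frame_hz Imaging rate (Hz).
#' @param baseline_s Pre-stimulus baseline span (s).
#' @param stim_s Train duration (s).
#' @param stim_hz Train frequency (Hz), metadata only.
#' @param record_s Total record length (s).
#' @param seed Optional integer seed.
#' @param experiment_id Identifier carried to the output.
#' @return A tibble of class `syph_boutons` with columns `bouton_id`,
#'   `time_s`, `f_percent` and attributes `onset_s`, `stim_end_s`, `truth`.
#' @examples
#' b <- simulate_syph_experiment(peak_dff = 161,
#'   decay = list(type = "constant_rate", rate_pct_per_s = 3.9),
#'   n_boutons = 20, noise_sd = 3, seed = 1)
#' analyze_syph(b)
#' @export
simulate_syph_experiment <- function(peak_dff = 161,
                                     decay = list(type = "constant_rate",
                                                  rate_pct_per_s = 3.9),
                                     n_boutons = 20,
                                     noise_sd = 3,
                                     bouton_cv = 0.2,
                                     frame_hz = 10,
                                     baseline_s = 10,
                                     stim_s = 10,
                                     stim_hz = 20,
                                     record_s = 60,
                                     seed = NULL,
                                     experiment_id = "exp1") {
  if (peak_dff < 0) stop_invalid("`peak_dff` must be >= 0.")
  if (n_boutons < 1) stop_invalid("`n_boutons` must be >= 1.")
  if (noise_sd < 0 || bouton_cv < 0) stop_invalid("Noise parameters must be >= 0.")
  if (!decay$type %in% c("constant_rate", "mono")) {
    stop_invalid('`decay$type` must be "constant_rate" or "mono".')
  }
  time_s <- seq(0, record_s, by = 1 / frame_hz)
  onset <- baseline_s
  t_peak <- onset + stim_s

  shape <- numeric(length(time_s))           # unit peak rise above baseline
  rise <- time_s >= onset & time_s <= t_peak
  shape[rise] <- (time_s[rise] - onset) / stim_s
  post <- time_s > t_peak
  tp <- time_s[post] - t_peak
  shape[post] <- switch(decay$type,
    constant_rate = pmax(0, 1 - decay$rate_pct_per_s / 100 * tp),
    mono = exp(-tp / decay$tau_s)
  )

  with_seed_if(seed, {
    factors <- if (bouton_cv > 0) {
      pmax(0.05, rnorm(n_boutons, 1, bouton_cv))
    } else {
      rep(1, n_boutons)
    }
    traces <- lapply(seq_len(n_boutons), function(b) {
      f <- 100 + peak_dff * factors[b] * shape
      if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
      tibble(bouton_id = sprintf("bouton_%02d", b), time_s = time_s,
             f_percent = f)
    })
    out <- dplyr::bind_rows(traces)
  })

  structure(
    out,
    onset_s = onset,
    stim_end_s = t_peak,
    experiment_id = experiment_id,
    truth = list(peak_dff = peak_dff, decay = decay, n_boutons = n_boutons,
                 noise_sd = noise_sd, bouton_cv = bouton_cv,
                 frame_hz = frame_hz, stim_hz = stim_hz, seed = seed),
    class = c("syph_boutons", class(out))
  )
}

#' Normalize bouton traces to baseline and average them
#'
#' Rescales each bouton trace so that its pre-stimulus mean equals 100%,
#' then averages boutons frame-by-frame (unweighted) into the experiment
#' trace. Input may be raw fluorescence in arbitrary units or already in
#' percent; only the pre-onset frames define the scale.
#'
#' @param boutons A tibble with columns `bouton_id`, `time_s`, and a
#'   fluorescence column (`f_percent` or `f_raw`); typically a
#'   `syph_boutons` object.
#' @param onset_s Stimulus onset time; taken from the object's attribute
#'   when present.
#' @param stim_end_s Stimulus end time; attribute default likewise.
#' @return A tibble of class `syph_experiment` with columns `time_s`,
#'   `f_percent`, `n_boutons`, and attributes `onset_s`, `stim_end_s`.
#' @export
normalize_and_average <- function(boutons, onset_s = NULL, stim_end_s = NULL) {
  onset_s <- onset_s %||% attr(boutons, "onset_s")
  stim_end_s <- stim_end_s %||% attr(boutons, "stim_end_s")
  if (is.null(onset_s)) stop_invalid("Stimulus onset time is required.")
  fcol <- intersect(c("f_percent", "f_raw"), names(boutons))[1]
  if (is.na(fcol)) stop_invalid("Need a fluorescence column `f_percent` or `f_raw`.")

  normed <- boutons |>
    dplyr::group_by(.data$bouton_id) |>
    dplyr::group_modify(function(df, key) {
      base <- df[[fcol]][df$time_s < onset_s]
      if (length(base) == 0L) {
        stop_insufficient("A bouton trace has no pre-stimulus baseline frames.")
      }
      df$f_percent <- df[[fcol]] * 100 / mean(base)
      df
    }) |>
    dplyr::ungroup()

  avg <- normed |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(f_percent = mean(.data$f_percent),
                     n_boutons = dplyr::n(), .groups = "drop")

  structure(
    avg,
    onset_s = onset_s,
    stim_end_s = stim_end_s %||% onset_s,
    experiment_id = attr(boutons, "experiment_id"),
    class = c("syph_experiment", class(avg))
  )
}

#' Peak fluorescence rise over baseline
#'
#' Maximum of the experiment-average trace minus the 100% baseline,
#' searched from stimulus onset to 5 s after stimulus end (the peak can lag
#' the train end slightly). Being a max over frames, the estimate carries a
#' positive noise bias bounded by about twice the experiment-average frame
#' noise SD.
#'
#' @param exp_trace A `syph_experiment` from [normalize_and_average()].
#' @param search_after_s Search extension past stimulus end (s).
#' @return Peak rise in percent (dF/F).
#' @export
compute_dff_peak <- function(exp_trace, search_after_s = 5) {
  onset <- attr(exp_trace, "onset_s")
  stim_end <- attr(exp_trace, "stim_end_s")
  sel <- exp_trace$time_s >= onset & exp_trace$time_s <= stim_end + search_after_s
  if (!any(sel)) stop_insufficient("No frames in the peak search window.")
  max(exp_trace$f_percent[sel]) - 100
}

#' Normalized initial fluorescence decay rate
#'
#' Minus the least-squares slope of the experiment trace over a window of
#' `window_s` seconds starting at the post-stimulus peak, expressed as
#' percent of the peak rise (dF/F) lost per second. The measurement window
#' covers the first seconds of decay; its length is configurable within the
#' 4-10 s range (default 6 s). Undefined (NA, with a warning) when the peak
#' rise is not positive.
#'
#' @param exp_trace A `syph_experiment`.
#' @param window_s Decay window length (s), between 4 and 10.
#' @return Normalized decay rate in %/s.
#' @export
compute_syph_rate_decay_n <- function(exp_trace, window_s = 6) {
  if (window_s < 4 || window_s > 10) {
    stop_invalid("`window_s` must lie within [4, 10] seconds.")
  }
  onset <- attr(exp_trace, "onset_s")
  stim_end <- attr(exp_trace, "stim_end_s")
  sel <- exp_trace$time_s >= onset & exp_trace$time_s <= stim_end + 5
  dff <- max(exp_trace$f_percent[sel]) - 100
  if (!is.finite(dff) || dff <= 0) {
    warn("Peak dF/F is not positive; normalized decay rate undefined.")
    return(NA_real_)
  }
  t_peak <- exp_trace$time_s[sel][which.max(exp_trace$f_percent[sel])]
  if (t_peak + window_s > max(exp_trace$time_s)) {
    stop_insufficient("Decay window extends beyond the record.")
  }
  win <- exp_trace$time_s >= t_peak & exp_trace$time_s <= t_peak + window_s
  slope <- ls_slope(exp_trace$time_s[win], exp_trace$f_percent[win])
  -slope / dff * 100
}

#' Mono-exponential fit of the fluorescence decay
#'
#' Alternative to the slope statistic: fits
#' `F(t) = plateau + A * exp(-(t - t_peak)/tau)` to the post-peak trace and
#' returns the time constant. Exposed because an initial rate can also be
#' derived from a fit as `dff/tau`.
#'
#' @param exp_trace A `syph_experiment`.
#' @return A one-row tibble with `tau_s`, `plateau`, `amplitude`,
#'   `converged`.
#' @export
fit_syph_decay <- function(exp_trace) {
  onset <- attr(exp_trace, "onset_s")
  stim_end <- attr(exp_trace, "stim_end_s")
  sel <- exp_trace$time_s >= onset & exp_trace$time_s <= stim_end + 5
  t_peak <- exp_trace$time_s[sel][which.max(exp_trace$f_percent[sel])]
  post <- exp_trace$time_s >= t_peak
  tt <- exp_trace$time_s[post] - t_peak
  yy <- exp_trace$f_percent[post]
  fit <- tryCatch({
    a0 <- max(yy[1] - min(yy), 1)
    minpack.lm::nlsLM(yy ~ plateau + A * exp(-tt / tau),
                      start = list(plateau = min(yy), A = a0,
                                   tau = max(tt) / 5),
                      lower = c(-Inf, 0, 0.1),
                      upper = c(Inf, Inf, 100 * max(tt)))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(tibble(tau_s = NA_real_, plateau = NA_real_, amplitude = NA_real_,
                  converged = FALSE))
  }
  cf <- coef(fit)
  tibble(tau_s = unname(cf["tau"]), plateau = unname(cf["plateau"]),
         amplitude = unname(cf["A"]), converged = TRUE)
}

#' Full per-experiment pHluorin quantification
#'
#' Normalizes and averages the bouton traces, then computes the peak dF/F,
#' the normalized initial decay rate, and the mono-exponential decay time
#' constant: one tidy row per experiment.
#'
#' @param boutons A `syph_boutons` tibble (or compatible data frame with
#'   `onset_s`/`stim_end_s` supplied).
#' @param window_s Decay window length (s).
#' @param onset_s,stim_end_s Stimulus epoch overrides.
#' @return A one-row tibble with `experiment_id`, `n_boutons`,
#'   `dff_percent`, `rate_decay_n_pct_per_s`, `tau_s`.
#' @export
analyze_syph <- function(boutons, window_s = 6, onset_s = NULL,
                         stim_end_s = NULL) {
  exp_trace <- normalize_and_average(boutons, onset_s, stim_end_s)
  fit <- fit_syph_decay(exp_trace)
  tibble(
    experiment_id = attr(exp_trace, "experiment_id") %||% "exp1",
    n_boutons = max(exp_trace$n_boutons),
    dff_percent = compute_dff_peak(exp_trace),
    rate_decay_n_pct_per_s = compute_syph_rate_decay_n(exp_trace, window_s),
    tau_s = fit$tau_s
  )
}
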