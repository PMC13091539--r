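#' Measure the capacitance jump evoked by a stimulus
#'
#' The jump (the exocytosis readout) is the difference between the
#' post-stimulus peak level and the pre-stimulus baseline. The baseline is
#' the mean of the last `baseline_s` seconds before stimulus onset. Because
#' the first `artifact_blank_s` of post-stimulus trace is unusable, the peak
#' is estimated from the first `peak_window_s` of clean samples:
#' `method = "extrapolate"` (default) fits a line over that window and takes
#' its intercept at stimulus end, cancelling the decay that has already
#' occurred during the artifact blank (bias < 0.5% for decay time constants
#' of 5 s and above); `method = "window_mean"` is the plain mean of the
#' window and underestimates the jump by roughly
#' `1 - exp(-(blank + window/2)/tau)`.
#'
#' @param rec A `cm_recording` tibble (see [simulate_cm_recording()]).
#' @param baseline_s Pre-onset baseline span (s).
#' @param peak_window_s Length of the clean post-artifact window used for
#'   the peak estimate (s).
#' @param method `"extrapolate"` or `"window_mean"`.
#' @return The capacitance jump in fF (length-1 numeric).
#' @export
measure_delta_cm_peak <- function(rec, baseline_s = 1, peak_window_s = 0.25,
                                  method = c("extrapolate", "window_mean")) {
  method <- match.arg(method)
  onset <- attr(rec, "onset_s") %||% 0
  stim_end <- attr(rec, "stim_end_s") %||% onset

  base_idx <- rec$time_s >= (onset - baseline_s) & rec$time_s < onset
  if (!any(base_idx)) stop_insufficient("No pre-stimulus baseline samples.")
  baseline <- mean(rec$cm_fF[base_idx])

  post <- rec$time_s >= stim_end & !rec$masked
  if (!any(post)) stop_insufficient("All post-stimulus samples are masked.")
  t_first <- min(rec$time_s[post])
  win <- post & rec$time_s < t_first + peak_window_s
  tw <- rec$time_s[win] - stim_end
  yw <- rec$cm_fF[win]

  peak <- if (method == "window_mean" || sum(win) < 3L) {
    mean(yw)
  } else {
    # Intercept at stimulus end of the LS line through the clean window.
    unname(coef(lm(yw ~ tw))[1])
  }
  peak - baseline
}

#' Fit an exponential model to the post-stimulus capacitance decay
#'
#' Least-squares fit of `Cm(t) = plateau + A * exp(-(t - t0)/tau)` (mono) or
#' `plateau + A1 * exp(-(t - t0)/tau1) + A2 * exp(-(t - t0)/tau2)` (bi) to
#' the unmasked samples after the stimulus, where `t0` is the first clean
#' sample. Fitted amplitudes are back-extrapolated to stimulus end
#' (`A * exp((t0 - stim_end)/tau)`), so they quantify the components of the
#' full jump rather than of the post-artifact remainder. The bi-exponential
#' fit reports components ordered so that `tau1 < tau2` and the rapid
#' amplitude share `weight1 = A1/(A1 + A2)`.
#' Starting values come from a log-linear fit to the tail (slow component)
#' whose residual is peeled to seed the rapid component; optimization is
#' bounded Levenberg-Marquardt with `tau` in `(0.01, 10 * window]`.
#' Non-convergence is reported (`converged = FALSE`, `model = "unfit"`),
#' never silent, and a time constant whose 95% CI spans the fitting window
#' is flagged `tau_uncertain`.
#'
#' @param rec A `cm_recording`.
#' @param model `"mono"` or `"bi"`.
#' @param t_max Optional end of the fit window, in seconds after stimulus
#'   end (default: whole record).
#' @return An object of class `cm_decay_fit`; see [tidy.cm_decay_fit()] and
#'   [glance.cm_decay_fit()].
#' @export
fit_cm_decay <- function(rec, model = c("mono", "bi"), t_max = NULL) {
  model <- match.arg(model)
  stim_end <- attr(rec, "stim_end_s") %||% 0
  keep <- rec$time_s >= stim_end & !rec$masked
  if (!is.null(t_max)) keep <- keep & rec$time_s <= stim_end + t_max
  if (sum(keep) < 20L) {
    stop_insufficient("Need at least 20 unmasked post-stimulus samples to fit.")
  }
  t0 <- min(rec$time_s[keep])
  tt <- rec$time_s[keep] - t0
  yy <- rec$cm_fF[keep]
  window <- max(tt)

  offset <- t0 - stim_end
  fit <- tryCatch(
    if (model == "mono") fit_mono(tt, yy, window, offset) else
      fit_bi(tt, yy, window, offset),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    res <- list(model = "unfit", requested_model = model, converged = FALSE,
                estimate = NULL, tau_uncertain = TRUE, sigma = NA_real_,
                window_s = window, t0_s = t0, n = length(tt),
                data = tibble(t_s = tt + t0, cm_fF = yy))
    class(res) <- "cm_decay_fit"
    return(res)
  }

  res <- c(fit, list(requested_model = model, window_s = window, t0_s = t0,
                     n = length(tt),
                     data = tibble(t_s = tt + t0, cm_fF = yy)))
  class(res) <- "cm_decay_fit"
  res
}

fit_mono <- function(tt, yy, window, offset = 0) {
  plateau0 <- mean(tail(yy, max(5L, round(0.05 * length(yy)))))
  a0 <- yy[1] - plateau0
  pos <- yy - plateau0
  tau0 <- if (a0 > 0 && any(pos > a0 * exp(-3) & tt < window / 2)) {
    sel <- pos > max(a0 * 1e-3, 1e-12) & tt < window / 2
    s <- ls_slope(tt[sel], log(pos[sel]))
    if (is.finite(s) && s < 0) -1 / s else window / 5
  } else {
    window / 5
  }
  tau0 <- min(max(tau0, 0.02), 10 * window)
  run_fit <- function(start) minpack.lm::nlsLM(
    yy ~ plateau + A * exp(-tt / tau),
    start = start,
    lower = c(-Inf, -Inf, 0.01),
    upper = c(Inf, Inf, 10 * window),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  # A start sitting exactly on the solution (noiseless traces) makes the
  # zero-residual gradient appear singular; retry from a nudged start.
  fit <- tryCatch(
    run_fit(list(plateau = plateau0, A = a0, tau = tau0)),
    error = function(e) run_fit(list(plateau = plateau0 + 0.05 * abs(a0) + 1e-3,
                                     A = 0.9 * a0, tau = 1.2 * tau0))
  )
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  scale_A <- exp(offset / cf["tau"])
  cf["A"] <- cf["A"] * scale_A
  se["A"] <- se["A"] * scale_A
  est <- tibble(
    term = c("plateau", "A", "tau"),
    estimate = unname(cf[c("plateau", "A", "tau")]),
    std_error = unname(se[c("plateau", "A", "tau")])
  )
  tau_se <- est$std_error[est$term == "tau"]
  list(model = "mono", converged = TRUE, estimate = est,
       tau_s = unname(cf["tau"]), amplitude_fF = unname(cf["A"]),
       plateau_fF = unname(cf["plateau"]),
       tau_uncertain = !is.finite(tau_se) || 1.96 * tau_se > window,
       sigma = tryCatch(summary(fit)$sigma, error = function(e) NA_real_))
}

fit_bi <- function(tt, yy, window, offset = 0) {
  plateau0 <- mean(tail(yy, max(5L, round(0.05 * length(yy)))))
  pos <- yy - plateau0
  # Slow component from the tail of the window.
  tail_sel <- tt > window / 3 & pos > max(max(pos) * 1e-3, 1e-12)
  s2 <- if (sum(tail_sel) >= 5L) ls_slope(tt[tail_sel], log(pos[tail_sel])) else NA_real_
  tau2_0 <- if (is.finite(s2) && s2 < 0) -1 / s2 else window / 3
  tau2_0 <- min(max(tau2_0, 0.1), 10 * window)
  a2_0 <- if (sum(tail_sel) >= 5L) {
    exp(mean(log(pos[tail_sel]) + tt[tail_sel] / tau2_0))
  } else {
    max(pos[1], 1e-6) / 2
  }
  # Rapid component from the peeled early residual.
  resid <- pos - a2_0 * exp(-tt / tau2_0)
  early <- tt < window / 4 & resid > max(max(resid) * 1e-3, 1e-12)
  s1 <- if (sum(early) >= 5L) ls_slope(tt[early], log(resid[early])) else NA_real_
  tau1_0 <- if (is.finite(s1) && s1 < 0) -1 / s1 else tau2_0 / 10
  tau1_0 <- min(max(tau1_0, 0.02), tau2_0)
  a1_0 <- max(pos[1] - a2_0, max(pos[1], 1e-6) / 4)

  run_fit <- function(start) minpack.lm::nlsLM(
    yy ~ plateau + A1 * exp(-tt / tau1) + A2 * exp(-tt / tau2),
    start = start,
    lower = c(-Inf, 0, 0.01, 0, 0.01),
    upper = c(Inf, Inf, 10 * window, Inf, 10 * window),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  fit <- tryCatch(
    run_fit(list(plateau = plateau0, A1 = a1_0, tau1 = tau1_0,
                 A2 = a2_0, tau2 = tau2_0)),
    error = function(e) run_fit(list(plateau = plateau0 + 1e-3,
                                     A1 = 0.9 * a1_0, tau1 = 0.8 * tau1_0,
                                     A2 = 0.9 * a2_0, tau2 = 1.2 * tau2_0))
  )
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 5), names(cf)))
  # Order components so tau1 is the rapid one.
  if (cf["tau1"] > cf["tau2"]) {
    cf <- cf[c("plateau", "A2", "tau2", "A1", "tau1")]
    se <- se[c("plateau", "A2", "tau2", "A1", "tau1")]
    names(cf) <- names(se) <- c("plateau", "A1", "tau1", "A2", "tau2")
  }
  for (k in 1:2) {
    scale_A <- exp(offset / cf[paste0("tau", k)])
    cf[paste0("A", k)] <- cf[paste0("A", k)] * scale_A
    se[paste0("A", k)] <- se[paste0("A", k)] * scale_A
  }
  est <- tibble(term = names(cf), estimate = unname(cf), std_error = unname(se))
  tau_se <- se[c("tau1", "tau2")]
  list(model = "bi", converged = TRUE, estimate = est,
       tau1_s = unname(cf["tau1"]), tau2_s = unname(cf["tau2"]),
       weight1 = unname(cf["A1"] / (cf["A1"] + cf["A2"])),
       plateau_fF = unname(cf["plateau"]),
       tau_uncertain = any(!is.finite(tau_se)) || any(1.96 * tau_se > window),
       sigma = tryCatch(summary(fit)$sigma, error = function(e) NA_real_))
}

#' @export
print.cm_decay_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<cm_decay_fit> unfit (", x$requested_model, " model did not converge)\n",
        sep = "")
    return(invisible(x))
  }
  if (x$model == "mono") {
    cat(sprintf("<cm_decay_fit> mono: tau = %.4g s, A = %.4g fF, plateau = %.4g fF%s\n",
                x$tau_s, x$amplitude_fF, x$plateau_fF,
                if (x$tau_uncertain) " [tau uncertain]" else ""))
  } else {
    cat(sprintf(
      "<cm_decay_fit> bi: tau1 = %.4g s (weight %.1f%%), tau2 = %.4g s, plateau = %.4g fF%s\n",
      x$tau1_s, 100 * x$weight1, x$tau2_s, x$plateau_fF,
      if (x$tau_uncertain) " [tau uncertain]" else ""))
  }
  invisible(x)
}

#' Tidy and glance methods for capacitance decay fits
#'
#' @param x A `cm_decay_fit` from [fit_cm_decay()].
#' @param ... Unused.
#' @return `tidy()` returns one row per fitted parameter with its standard
#'   error; `glance()` returns a one-row model summary.
#' @export
tidy.cm_decay_fit <- function(x, ...) {
  if (is.null(x$estimate)) {
    return(tibble(term = character(), estimate = numeric(),
                  std_error = numeric()))
  }
  x$estimate
}

#' @rdname tidy.cm_decay_fit
#' @export
glance.cm_decay_fit <- function(x, ...) {
  tibble(
    model = x$model,
    converged = x$converged,
    tau_s = if (x$model == "mono") x$tau_s else NA_real_,
    tau1_s = if (x$model == "bi") x$tau1_s else NA_real_,
    tau2_s = if (x$model == "bi") x$tau2_s else NA_real_,
    weight1 = if (x$model == "bi") x$weight1 else NA_real_,
    tau_uncertain = x$tau_uncertain,
    sigma = x$sigma,
    n = x$n,
    window_s = x$window_s
  )
}

# Protocol-dependent initial-decay-rate windows, in seconds after stimulus
# end. The single-pulse window also serves the 1 s step, for which no
# dedicated window is defined.
rate_decay_window <- function(protocol) {
  switch(protocol$name,
    depol_20ms = c(0.5, 4),
    depol_20msX10 = c(0.5, 1.5),
    depol_1s = c(0.5, 4)
  )
}

#' Initial capacitance decay rate after stimulation
#'
#' The endocytosis-rate statistic: minus the least-squares linear slope of
#' the capacitance over a protocol-dependent window after stimulus end
#' (0.5-4 s after a single 20 ms step, 0.5-1.5 s after the 10 x 20 ms
#' train), so a decaying trace yields a positive rate in fF/s.
#'
#' @param rec A `cm_recording`.
#' @param window Optional `c(start, end)` override, seconds after stimulus
#'   end.
#' @return Decay rate in fF/s.
#' @export
compute_rate_decay <- function(rec, window = NULL) {
  stim_end <- attr(rec, "stim_end_s") %||% 0
  protocol <- attr(rec, "protocol")
  window <- window %||% rate_decay_window(protocol)
  if (length(window) != 2L || window[2] <= window[1]) {
    stop_invalid("`window` must be c(start, end) with end > start.")
  }
  if (stim_end + window[2] > max(rec$time_s)) {
    stop_insufficient("Rate-decay window extends beyond the record.")
  }
  sel <- rec$time_s >= stim_end + window[1] &
    rec$time_s <= stim_end + window[2] & !rec$masked
  if (sum(sel) < 2L) stop_insufficient("Fewer than 2 samples in the rate window.")
  -ls_slope(rec$time_s[sel], rec$cm_fF[sel])
}

#' Normalized decay rate and the first-second retrieval identity
#'
#' `compute_rate_decay_n()` divides the initial decay rate by the
#' capacitance jump, giving the fraction of the jump retrieved per second
#' (units 1/s); it is undefined (NA, with a warning) when the jump is not
#' positive. For a mono-exponential decay with time constant `tau`,
#' `first_second_retrieval()` returns `1 - exp(-1/tau)`, the fraction of
#' the jump retrieved in the first second — the interpretive equivalent of
#' the normalized rate (0.0935, i.e. ~9%, at tau = 10.2 s).
#'
#' @param rate_decay_fF_per_s Initial decay rate (fF/s).
#' @param delta_cm_peak_fF Capacitance jump (fF).
#' @param tau_s Mono-exponential time constant (s).
#' @return A rate in 1/s (or a fraction for `first_second_retrieval()`).
#' @export
compute_rate_decay_n <- function(rate_decay_fF_per_s, delta_cm_peak_fF) {
  out <- rate_decay_fF_per_s / delta_cm_peak_fF
  bad <- !is.na(delta_cm_peak_fF) & delta_cm_peak_fF <= 0
  if (any(bad)) {
    warn("Normalized decay rate undefined where the capacitance jump is <= 0.")
    out[bad] <- NA_real_
  }
  out
}

#' @rdname compute_rate_decay_n
#' @export
first_second_retrieval <- function(tau_s) 1 - exp(-1 / tau_s)

#' Total decay fraction at a fixed time after stimulation
#'
#' Fraction of the capacitance jump retrieved by `at_s` seconds after
#' stimulus end (or record end if sooner), using the mean of the final
#' second of trace before that time as the end level. Values above 1
#' indicate retrieval beyond the jump (overshoot).
#'
#' @param rec A `cm_recording`.
#' @param delta_cm_peak_fF The jump; measured from `rec` if omitted.
#' @param at_s Evaluation time, seconds after stimulus end.
#' @param baseline_s Pre-onset baseline span (s).
#' @return Total decay as a fraction of the jump.
#' @export
measure_total_decay_fraction <- function(rec, delta_cm_peak_fF = NULL,
                                         at_s = 60, baseline_s = 1) {
  onset <- attr(rec, "onset_s") %||% 0
  stim_end <- attr(rec, "stim_end_s") %||% onset
  jump <- delta_cm_peak_fF %||% measure_delta_cm_peak(rec, baseline_s)
  if (is.na(jump) || jump <= 0) return(NA_real_)
  baseline <- mean(rec$cm_fF[rec$time_s >= onset - baseline_s & rec$time_s < onset])
  t_end <- min(max(rec$time_s), stim_end + at_s)
  end_sel <- rec$time_s > t_end - 1 & rec$time_s <= t_end & !rec$masked
  if (!any(end_sel)) stop_insufficient("No samples at the decay evaluation time.")
  end_dev <- mean(rec$cm_fF[end_sel]) - baseline
  1 - end_dev / jump
}

#' Classify a recording into one of five endocytic modes
#'
#' The five-group classification of post-stimulus capacitance decay:
#' overshoot (total decay > 130% of the jump), no-endocytosis (total decay
#' < 30%), and otherwise by the dominant decay time constant — ultrafast
#' (tau < 0.6 s), fast (0.6 s <= tau <= 6 s, boundaries inclusive), slow
#' (tau > 6 s). The amplitude checks take precedence over the time
#' constant; a recording with no usable time constant and an intermediate
#' decay is `"unclassified"`. Vectorized over both arguments.
#'
#' @param total_decay_fraction Total decay as a fraction of the jump
#'   (1.4 = 140%).
#' @param tau_s Dominant decay time constant (s); NA when unavailable.
#' @return A factor with levels `no_endo`, `slow`, `fast`, `ultrafast`,
#'   `overshoot`, `unclassified`.
#' @examples
#' classify_endocytic_mode(c(1.4, 0.2, 0.8, 0.8, 0.8), c(NA, NA, 0.5, 3, 10))
#' @export
classify_endocytic_mode <- function(total_decay_fraction, tau_s = NA_real_) {
  n <- max(length(total_decay_fraction), length(tau_s))
  frac <- rep_len(total_decay_fraction, n)
  tau <- rep_len(tau_s, n)
  mode <- rep("unclassified", n)
  by_tau <- !is.na(tau)
  mode[by_tau & tau < 0.6] <- "ultrafast"
  mode[by_tau & tau >= 0.6 & tau <= 6] <- "fast"
  mode[by_tau & tau > 6] <- "slow"
  has_frac <- !is.na(frac)
  mode[has_frac & frac < 0.3] <- "no_endo"
  mode[has_frac & frac > 1.3] <- "overshoot"
  factor(mode, levels = c("no_endo", "slow", "fast", "ultrafast",
                          "overshoot", "unclassified"))
}

# Printed calcium-current bins (pA magnitudes) used to group cells.
ica_bins <- list(low = c(160, 360), mid = c(400, 900), high = c(1000, 1800))

#' Measure the peak calcium current and assign its amplitude bin
#'
#' Peak inward-current magnitude during the stimulus epoch, binned into the
#' reported groups 160-360 pA (`low`), 400-900 pA (`mid`) and 1000-1800 pA
#' (`high`); magnitudes falling in the gaps or outside are `out_of_bin`. A
#' missing calcium-current trace is flagged `absent`.
#'
#' @param rec A `cm_recording`.
#' @return A one-row tibble with `ica_peak_pA` and `ica_bin`.
#' @export
measure_ica <- function(rec) {
  onset <- attr(rec, "onset_s") %||% 0
  stim_end <- attr(rec, "stim_end_s") %||% onset
  if (!"ica_pA" %in% names(rec) || all(is.na(rec$ica_pA))) {
    return(tibble(ica_peak_pA = NA_real_, ica_bin = "absent"))
  }
  sel <- rec$time_s >= onset & rec$time_s <= stim_end
  inward <- pmax(-rec$ica_pA[sel], 0)
  peak <- if (length(inward)) max(inward, na.rm = TRUE) else 0
  bin <- "out_of_bin"
  for (nm in names(ica_bins)) {
    rng <- ica_bins[[nm]]
    if (!is.na(peak) && peak >= rng[1] && peak <= rng[2]) bin <- nm
  }
  tibble(ica_peak_pA = peak, ica_bin = bin)
}

#' Full per-recording capacitance kinetics
#'
#' Runs the whole per-recording analysis: capacitance jump, exponential
#' decay fit (`"auto"` picks mono for single pulses and bi for the train),
#' initial and normalized decay rates, total decay fraction, endocytic-mode
#' classification, and calcium-current peak/bin — one tidy row per
#' recording, ready to be stacked across cells with [dplyr::bind_rows()].
#'
#' @param rec A `cm_recording`.
#' @param model `"auto"`, `"mono"` or `"bi"`.
#' @param rate_window Optional rate-decay window override (s after stimulus
#'   end).
#' @param decay_at_s Evaluation time for the total decay fraction.
#' @return A one-row tibble (class `cm_kinetics` via its columns): ids,
#'   `delta_cm_peak_fF`, fit parameters, `rate_decay_fF_per_s`,
#'   `rate_decay_n_per_s`, `first_second_retrieval`,
#'   `total_decay_fraction`, `mode`, `ica_peak_pA`, `ica_bin`.
#' @export
analyze_cm <- function(rec, model = c("auto", "mono", "bi"),
                       rate_window = NULL, decay_at_s = 60) {
  model <- match.arg(model)
  protocol <- attr(rec, "protocol")
  if (model == "auto") {
    model <- if (!is.null(protocol) && protocol$name == "depol_20msX10") "bi" else "mono"
  }
  jump <- measure_delta_cm_peak(rec)
  fit <- fit_cm_decay(rec, model)
  rate <- compute_rate_decay(rec, rate_window)
  rate_n <- compute_rate_decay_n(rate, jump)
  frac <- measure_total_decay_fraction(rec, jump, at_s = decay_at_s)
  tau_dom <- if (!fit$converged) {
    NA_real_
  } else if (fit$model == "mono") {
    fit$tau_s
  } else if (fit$weight1 >= 0.5) fit$tau1_s else fit$tau2_s
  ica <- measure_ica(rec)
  tibble(
    recording_id = rec$recording_id[1],
    cell_id = attr(rec, "cell_id") %||% rec$recording_id[1],
    condition = attr(rec, "condition") %||% NA_character_,
    protocol = if (!is.null(protocol)) protocol$name else NA_character_,
    delta_cm_peak_fF = jump,
    fit_model = fit$model,
    converged = fit$converged,
    tau_s = if (fit$converged && fit$model == "mono") fit$tau_s else NA_real_,
    tau1_s = if (fit$converged && fit$model == "bi") fit$tau1_s else NA_real_,
    tau2_s = if (fit$converged && fit$model == "bi") fit$tau2_s else NA_real_,
    weight1 = if (fit$converged && fit$model == "bi") fit$weight1 else NA_real_,
    tau_uncertain = fit$tau_uncertain,
    rate_decay_fF_per_s = rate,
    rate_decay_n_per_s = rate_n,
    first_second_retrieval = if (fit$converged && fit$model == "mono") {
      first_second_retrieval(fit$tau_s)
    } else {
      NA_real_
    },
    total_decay_fraction = frac,
    mode = as.character(classify_endocytic_mode(frac, tau_dom)),
    ica_peak_pA = ica$ica_peak_pA,
    ica_bin = ica$ica_bin
  )
}
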