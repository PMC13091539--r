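# Fusion-event detection and classification from three-channel spot traces.
#
# Channels: f_ph (membrane label, weak excitation), f_655 (bath dye filling
# the vesicle lumen, strong excitation -> bleaches when the pore closes),
# f_ffn (vesicular content, released on fusion). All threshold comparisons
# run on lightly smoothed, baseline-subtracted series so the rules stay
# stable at realistic frame noise.

# Smoothing width (frames) used by the classifiers.
.spot_smooth_width <- 5L

# First sustained crossing below `level`: index of the first frame below
# `level` whose `sustain` following frames are also below; NA if none.
sustained_below <- function(x, level, sustain = 3L) {
  below <- x < level
  n <- length(x)
  for (i in seq_len(n)) {
    if (below[i]) {
      hi <- min(n, i + sustain - 1L)
      if (all(below[i:hi])) return(i)
    }
  }
  NA_integer_
}

#' Detect the fusion onset in a spot trace
#'
#' Fusion is the sudden joint appearance of the membrane-label and bath-dye
#' spot with concurrent content release: the onset is the first frame where
#' `f_ph` and `f_655` both exceed their baseline mean plus
#' `k_sigma * baseline SD` within the same 3-frame window, and `f_ffn`
#' begins a sustained decline within plus or minus 2 frames. A rise without
#' the second channel, or without content release, is rejected as a
#' single-channel artifact.
#'
#' @param trace A `spot_trace` (or a data frame with `time_s`, `f_ph`,
#'   `f_655`, `f_ffn`).
#' @param k_sigma Threshold in baseline SDs.
#' @param baseline_s Baseline span used for the channel statistics (s);
#'   the trace must start with at least this much pre-event recording.
#' @return The onset time in seconds, or `NA_real_` when no fusion onset is
#'   found.
#' @export
detect_fusion_onset <- function(trace, k_sigma = 4, baseline_s = 1) {
  dt <- median(diff(trace$time_s))
  n_base <- sum(trace$time_s < trace$time_s[1] + baseline_s)
  if (n_base < max(3L, floor(baseline_s / dt) - 1L)) {
    stop_insufficient("Need at least 1 s of pre-event baseline frames.")
  }
  if (all(is.na(trace$f_ffn))) return(NA_real_)

  base_idx <- seq_len(n_base)
  thr <- function(x) {
    mean(x[base_idx]) + k_sigma * max(sd(x[base_idx]), 1e-9)
  }
  over_ph <- trace$f_ph > thr(trace$f_ph)
  over_655 <- trace$f_655 > thr(trace$f_655)

  n <- nrow(trace)
  sd_ffn <- max(sd(trace$f_ffn[base_idx]), 1e-9)
  slope_frames <- max(5L, round(1 / dt))

  for (i in which(over_ph)) {
    win <- i:min(n, i + 2L)
    if (!any(over_655[win]) && (i == 1L || !any(over_655[max(1L, i - 2L):i]))) next
    # Content channel must start a sustained decline within +/- 2 frames.
    j0 <- max(1L, i - 2L)
    j1 <- min(n, j0 + slope_frames)
    if (j1 - j0 < 4L) next
    seg <- trace$f_ffn[j0:j1]
    third <- max(2L, length(seg) %/% 3L)
    drop <- mean(seg[seq_len(third)], na.rm = TRUE) -
      mean(seg[(length(seg) - third + 1L):length(seg)], na.rm = TRUE)
    min_drop <- max(k_sigma * sd_ffn / sqrt(third), 1e-9)
    if (is.finite(drop) && drop > min_drop) return(trace$time_s[i])
  }
  NA_real_
}

#' Classify a fusion event as close-, stay- or shrink-fusion
#'
#' Decision rules, applied to smoothed baseline-subtracted channels after
#' `onset_s` and in this order:
#' \enumerate{
#'   \item \strong{shrink_fusion} — both channels decline (final level below
#'     `phi_sustain` of the post-onset peak), the declines are parallel
#'     (Pearson r at least `rho_parallel` over the decline segment), and
#'     the spot size, when available, shows a net decrease above 20%; the
#'     size criterion is what separates a shrinking spot from a closed
#'     vesicle whose membrane label later decays.
#'   \item \strong{close_fusion} — the bath-dye channel dims below
#'     `theta_dim` of its post-onset peak while the membrane label is still
#'     at or above `phi_sustain` of its own peak, or the membrane-label
#'     decline lags the dye dimming by at least `min_delay_frames`.
#'     `closure_time_s` is the onset-to-half-dimming interval (midpoint
#'     between the dye peak and its post-decay floor, interpolated).
#'   \item \strong{stay_fusion} — both channels end at or above
#'     `phi_sustain` of their peaks; `censored = TRUE` when the record ends
#'     less than 30 s after onset, since pore closure is observed up to
#'     about 30 s after fusion.
#'   \item Anything else is \strong{ambiguous} (a value, not an error).
#' }
#'
#' @param trace A `spot_trace`.
#' @param onset_s Fusion onset from [detect_fusion_onset()].
#' @param theta_dim Dimming threshold (fraction of post-onset peak).
#' @param phi_sustain Sustained threshold (fraction of post-onset peak).
#' @param min_delay_frames Membrane-vs-dye decline lag distinguishing
#'   pinch-off from parallel loss (frames).
#' @param rho_parallel Minimum Pearson correlation for a parallel decline.
#' @return A one-row tibble: `cell_id`, `spot_id`, `onset_s`, `mode`,
#'   `closure_time_s` (close-fusion only), `censored`.
#' @export
classify_fusion_mode <- function(trace, onset_s,
                                 theta_dim = 0.5, phi_sustain = 0.7,
                                 min_delay_frames = 3L, rho_parallel = 0.9) {
  ids <- list(cell_id = trace$cell_id[1], spot_id = trace$spot_id[1])
  if (is.na(onset_s)) {
    return(tibble(cell_id = ids$cell_id, spot_id = ids$spot_id,
                  onset_s = NA_real_, mode = "ambiguous",
                  closure_time_s = NA_real_, censored = NA))
  }
  dt <- median(diff(trace$time_s))
  base_idx <- trace$time_s < onset_s
  base_ph <- mean(trace$f_ph[base_idx])
  base_655 <- mean(trace$f_655[base_idx])

  post <- trace$time_s >= onset_s
  t_post <- trace$time_s[post]
  ph <- roll_mean(trace$f_ph[post], .spot_smooth_width) - base_ph
  a655 <- roll_mean(trace$f_655[post], .spot_smooth_width) - base_655
  size <- if (all(is.na(trace$size_nm))) NULL else {
    roll_mean(trace$size_nm[post], .spot_smooth_width)
  }

  peak_ph <- max(ph)
  peak_655 <- max(a655)
  tail_n <- max(3L, round(0.5 / dt))
  final_ph <- mean(tail(ph, tail_n))
  final_655 <- mean(tail(a655, tail_n))

  declined_ph <- final_ph < phi_sustain * peak_ph
  declined_655 <- final_655 < phi_sustain * peak_655
  # Lag between the two channels crossing the same fractional level; a deep
  # crossing is far more noise-robust than a decline-onset estimate.
  cross_ph <- sustained_below(ph, phi_sustain * peak_ph)
  cross_655 <- sustained_below(a655, phi_sustain * peak_655)
  lag_frames <- if (!is.na(cross_ph) && !is.na(cross_655)) {
    cross_ph - cross_655
  } else {
    NA_integer_
  }

  # (1) shrink-fusion: parallel decline of both channels with a shrinking
  # spot. The correlation is taken over the decline proper (from the first
  # sustained drop below 90% of peak until both channels reach 10% of
  # peak), not over the post-decay noise floor.
  if (declined_ph && declined_655) {
    from <- min(sustained_below(ph, 0.9 * peak_ph),
                sustained_below(a655, 0.9 * peak_655), na.rm = TRUE)
    done <- which(ph < 0.1 * peak_ph & a655 < 0.1 * peak_655)
    to <- if (any(done > from)) min(done[done > from]) else length(ph)
    seg <- from:to
    r <- if (length(seg) >= 3L) suppressWarnings(cor(ph[seg], a655[seg])) else NA_real_
    size_ok <- if (is.null(size)) TRUE else {
      size_start <- mean(head(size, tail_n))
      size_end <- mean(tail(size, tail_n))
      is.finite(size_start) && size_start > 0 &&
        (size_start - size_end) / size_start > 0.2
    }
    if (is.finite(r) && r >= rho_parallel && size_ok) {
      return(tibble(cell_id = ids$cell_id, spot_id = ids$spot_id,
                    onset_s = onset_s, mode = "shrink_fusion",
                    closure_time_s = NA_real_, censored = FALSE))
    }
  }

  # (2) close-fusion: dye dims while the membrane label holds, or the
  # membrane decline lags the dye decline.
  dim_while_high <- any(a655 < theta_dim * peak_655 & ph >= phi_sustain * peak_ph)
  lagged <- declined_655 && !is.na(lag_frames) && lag_frames >= min_delay_frames
  if (declined_655 && (dim_while_high || lagged)) {
    floor_655 <- min(a655[which.max(a655):length(a655)])
    half_level <- (peak_655 + floor_655) / 2
    t_half <- cross_below(t_post, a655, half_level)
    return(tibble(cell_id = ids$cell_id, spot_id = ids$spot_id,
                  onset_s = onset_s, mode = "close_fusion",
                  closure_time_s = t_half - onset_s, censored = FALSE))
  }

  # (3) stay-fusion: both channels sustained to record end.
  if (final_ph >= phi_sustain * peak_ph && final_655 >= phi_sustain * peak_655) {
    return(tibble(cell_id = ids$cell_id, spot_id = ids$spot_id,
                  onset_s = onset_s, mode = "stay_fusion",
                  closure_time_s = NA_real_,
                  censored = (max(trace$time_s) - onset_s) < 30))
  }

  tibble(cell_id = ids$cell_id, spot_id = ids$spot_id,
         onset_s = onset_s, mode = "ambiguous",
         closure_time_s = NA_real_, censored = NA)
}

#' Detect pore closure of a pre-existing spot
#'
#' A pre-existing spot (present before stimulation, no content channel)
#' closed its pore when the strongly excited bath dye bleaches — `f_655`
#' decays below `theta_dim` of its initial level — while the weakly excited
#' membrane label stays at or above `phi_sustain` of its initial level
#' through the dimming epoch (or declines only after a lag of at least
#' `min_delay_frames`). A parallel loss of both channels is not pore
#' closure.
#'
#' @param trace A `spot_trace` with `spot_kind = "pre_spot"` (any
#'   two-channel trace works).
#' @param theta_dim,phi_sustain,min_delay_frames As in
#'   [classify_fusion_mode()], applied to the initial levels.
#' @param initial_s Span used for the initial level (s).
#' @return `TRUE` if the spot underwent pore closure, else `FALSE`.
#' @export
detect_pre_close <- function(trace, theta_dim = 0.5, phi_sustain = 0.7,
                             min_delay_frames = 3L, initial_s = 1) {
  init_idx <- trace$time_s < trace$time_s[1] + initial_s
  if (sum(init_idx) < 3L) stop_insufficient("Need >= 1 s of initial frames.")
  ph <- roll_mean(trace$f_ph, .spot_smooth_width)
  a655 <- roll_mean(trace$f_655, .spot_smooth_width)
  init_ph <- mean(ph[init_idx])
  init_655 <- mean(a655[init_idx])

  dim_i <- sustained_below(a655, theta_dim * init_655)
  if (is.na(dim_i)) return(FALSE)

  dec_655 <- sustained_below(a655, 0.85 * init_655)
  dec_ph <- sustained_below(ph, 0.85 * init_ph)

  # Membrane label must hold through the dimming epoch...
  epoch <- seq(if (is.na(dec_655)) 1L else dec_655, dim_i)
  held <- all(ph[epoch] >= phi_sustain * init_ph)
  # ...or decline only after a pinch-off lag.
  lagged <- !is.na(dec_ph) && !is.na(dec_655) &&
    (dec_ph - dec_655) >= min_delay_frames
  held || lagged
}

#' Release time: the 20%-80% decay time of the content channel
#'
#' The release-time statistic of the vesicular content (false
#' neurotransmitter) channel: with span = pre-onset plateau minus
#' post-decay floor, the interval between the trace first crossing 20%
#' decayed and first crossing 80% decayed, both linearly interpolated
#' between frames. Equals `tau * ln 4` for an exponential release with time
#' constant `tau`, and 0.6 of the total duration for a linear ramp. When
#' the decay has not completed by record end (still declining, or no
#' measurable span) the value is censored (`NA` with `censored = TRUE`).
#'
#' @param trace A `spot_trace` with an `f_ffn` channel.
#' @param onset_s Fusion onset (s).
#' @return A one-row tibble with `t_ffn_s` and `censored`.
#' @export
compute_t_ffn <- function(trace, onset_s) {
  if (all(is.na(trace$f_ffn))) {
    stop_invalid("Trace has no content (`f_ffn`) channel.")
  }
  dt <- median(diff(trace$time_s))
  pre <- trace$time_s < onset_s
  if (!any(pre)) stop_insufficient("No pre-onset frames for the plateau.")
  plateau <- mean(trace$f_ffn[pre])

  post <- trace$time_s >= onset_s
  t_post <- trace$time_s[post]
  y <- trace$f_ffn[post]
  tail_n <- max(3L, round(0.5 / dt))
  floor_est <- mean(tail(y, tail_n))
  span <- plateau - floor_est

  # Censored when there is no measurable decay span or the trace is still
  # declining at record end (end slope steeper than 2% of span per second).
  end_slope <- ls_slope(tail(t_post, tail_n), tail(y, tail_n))
  still_declining <- is.finite(end_slope) && -end_slope > 0.02 * max(span, 1e-12)
  if (span <= .Machine$double.eps^0.5 * max(abs(plateau), 1) || span <= 0 ||
      still_declining) {
    return(tibble(t_ffn_s = NA_real_, censored = TRUE))
  }

  t20 <- cross_below(t_post, y, plateau - 0.2 * span)
  t80 <- cross_below(t_post, y, plateau - 0.8 * span)
  if (is.na(t20) || is.na(t80)) {
    return(tibble(t_ffn_s = NA_real_, censored = TRUE))
  }
  tibble(t_ffn_s = t80 - t20, censored = FALSE)
}

#' Detect and classify every spot in a measurement table
#'
#' Workhorse over a long-format table of per-frame spot measurements:
#' fusion candidates go through onset detection, mode classification and
#' release-time measurement; pre-existing spots go through pore-closure
#' detection. Spots whose fusion onset is not detected are dropped from the
#' event table (they never fused).
#'
#' @param spots A data frame with columns `cell_id`, `spot_id`,
#'   `spot_kind` (`"fusion_candidate"` or `"pre_spot"`), `time_s`, `f_ph`,
#'   `f_655`, `f_ffn`, and optionally `size_nm`.
#' @param k_sigma,theta_dim,phi_sustain,min_delay_frames,rho_parallel
#'   Detection/classification thresholds (see the individual functions).
#' @return A list of two tibbles: `events` (one row per fused spot:
#'   `cell_id`, `spot_id`, `onset_s`, `mode`, `closure_time_s`,
#'   `censored`, `t_ffn_s`, `t_ffn_censored`) and `pre_spots` (`cell_id`,
#'   `spot_id`, `closed`).
#' @export
classify_fusion_table <- function(spots, k_sigma = 4, theta_dim = 0.5,
                                  phi_sustain = 0.7, min_delay_frames = 3L,
                                  rho_parallel = 0.9) {
  if (!"size_nm" %in% names(spots)) spots$size_nm <- NA_real_
  split_spots <- split(spots, list(spots$cell_id, spots$spot_id), drop = TRUE)

  events <- list()
  pre <- list()
  for (tr in split_spots) {
    tr <- dplyr::arrange(tr, .data$time_s)
    if (tr$spot_kind[1] == "pre_spot") {
      pre[[length(pre) + 1L]] <- tibble(
        cell_id = tr$cell_id[1], spot_id = tr$spot_id[1],
        closed = detect_pre_close(tr, theta_dim, phi_sustain, min_delay_frames)
      )
    } else {
      onset <- detect_fusion_onset(tr, k_sigma)
      if (is.na(onset)) next
      ev <- classify_fusion_mode(tr, onset, theta_dim, phi_sustain,
                                 min_delay_frames, rho_parallel)
      tf <- compute_t_ffn(tr, onset)
      ev$t_ffn_s <- tf$t_ffn_s
      ev$t_ffn_censored <- tf$censored
      events[[length(events) + 1L]] <- ev
    }
  }
  list(
    events = if (length(events)) dplyr::bind_rows(events) else
      tibble(cell_id = character(), spot_id = character(),
             onset_s = numeric(), mode = character(),
             closure_time_s = numeric(), censored = logical(),
             t_ffn_s = numeric(), t_ffn_censored = logical()),
    pre_spots = if (length(pre)) dplyr::bind_rows(pre) else
      tibble(cell_id = character(), spot_id = character(), closed = logical())
  )
}

#' Per-cell fusion summary with the small-cell exclusion rule
#'
#' Aggregates classified events per cell: event counts by mode, the
#' probability of a fusion spot to undergo close-fusion, the probability of
#' a pre-existing spot to close its pore, and the mean release time over
#' non-censored events. Cells with fewer than `min_events` fusion events
#' are flagged `excluded = TRUE` (kept in the output, but meant to be
#' dropped from group aggregates to avoid small-denominator bias); the
#' pre-close probability is `NA` for cells without pre-existing spots.
#'
#' @param events Event tibble from [classify_fusion_table()].
#' @param pre_spots Pre-spot tibble from [classify_fusion_table()]
#'   (optional).
#' @param min_events Exclusion threshold on the number of fusion events.
#' @return A tibble with one row per cell.
#' @export
summarize_fusion_cells <- function(events, pre_spots = NULL, min_events = 5L) {
  cell_ev <- events |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_fusion_events = dplyr::n(),
      n_close = sum(.data$mode == "close_fusion"),
      n_stay = sum(.data$mode == "stay_fusion"),
      n_shrink = sum(.data$mode == "shrink_fusion"),
      n_ambiguous = sum(.data$mode == "ambiguous"),
      mean_t_ffn_s = if (any(!.data$t_ffn_censored & !is.na(.data$t_ffn_s))) {
        mean(.data$t_ffn_s[!.data$t_ffn_censored], na.rm = TRUE)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(prob_close_fusion = .data$n_close / .data$n_fusion_events)
  if (!is.null(pre_spots) && nrow(pre_spots) > 0) {
    cell_pre <- pre_spots |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(n_pre_spots = dplyr::n(),
                       prob_pre_close = mean(.data$closed), .groups = "drop")
    cell_ev <- dplyr::full_join(cell_ev, cell_pre, by = "cell_id")
    cell_ev$n_fusion_events[is.na(cell_ev$n_fusion_events)] <- 0L
  } else {
    cell_ev$n_pre_spots <- 0L
    cell_ev$prob_pre_close <- NA_real_
  }
  cell_ev$n_pre_spots[is.na(cell_ev$n_pre_spots)] <- 0L
  cell_ev |>
    dplyr::mutate(excluded = .data$n_fusion_events < min_events)
}
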