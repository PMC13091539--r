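# ggplot2 displays for the main result types. Masked capacitance samples
# are drawn greyed-out rather than hidden, mirroring how the analyzers
# treat them.

#' Plot a capacitance recording
#'
#' Capacitance versus time with the artifact-masked samples greyed out and
#' the stimulus epoch shaded.
#'
#' @param object A `cm_recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cm_recording <- function(object, ...) {
  stim_end <- attr(object, "stim_end_s") %||% 0
  onset <- attr(object, "onset_s") %||% 0
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$cm_fF)) +
    ggplot2::annotate("rect", xmin = onset, xmax = stim_end,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(colour = .data$masked, group = 1),
                       show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "grey70")) +
    ggplot2::labs(x = "Time from stimulus onset (s)", y = "Cm (fF)",
                  title = object$recording_id[1]) +
    ggplot2::theme_classic()
}

#' Plot a capacitance decay fit over its data
#'
#' @param object A `cm_decay_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cm_decay_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$t_s, y = .data$cm_fF)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "Time (s)", y = "Cm (fF)") +
    ggplot2::theme_classic()
  if (object$converged) {
    tt <- object$data$t_s - object$t0_s
    est <- setNames(object$estimate$estimate, object$estimate$term)
    yhat <- if (object$model == "mono") {
      est["plateau"] + est["A"] * exp(-tt / est["tau"])
    } else {
      est["plateau"] + est["A1"] * exp(-tt / est["tau1"]) +
        est["A2"] * exp(-tt / est["tau2"])
    }
    p <- p + ggplot2::geom_line(
      data = tibble(t_s = object$data$t_s, cm_fF = yhat),
      colour = "firebrick", linewidth = 0.8
    )
  }
  p
}

#' Plot a pHluorin experiment-average trace
#'
#' @param object A `syph_experiment` from [normalize_and_average()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.syph_experiment <- function(object, ...) {
  onset <- attr(object, "onset_s")
  stim_end <- attr(object, "stim_end_s")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$f_percent)) +
    ggplot2::annotate("segment", x = onset, xend = stim_end, y = 95, yend = 95,
                      linewidth = 2) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "F (% of baseline)") +
    ggplot2::theme_classic()
}

#' Plot a three-channel fusion-spot trace
#'
#' Channels are faceted (membrane label, bath dye, content, spot size) on
#' a shared time axis.
#'
#' @param object A `spot_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spot_trace <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(dplyr::any_of(c("f_ph", "f_655", "f_ffn", "size_nm")),
                        names_to = "channel", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(channel = factor(.data$channel,
                                   levels = c("f_ph", "f_655", "f_ffn",
                                              "size_nm")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), ncol = 1,
                        scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(f_ph = "forestgreen",
                                            f_655 = "firebrick",
                                            f_ffn = "steelblue",
                                            size_nm = "grey30")) +
    ggplot2::labs(x = "Time (s)", y = NULL,
                  title = paste(object$cell_id[1], object$spot_id[1])) +
    ggplot2::theme_classic()
}

#' Bar plot of EM densities by condition and timepoint
#'
#' Group means with s.e.m. error bars for either the HRP(+) vesicle
#' density or the bulk-endosome area density.
#'
#' @param densities Output of [em_profile_densities()] (must carry
#'   `condition` and `timepoint`).
#' @param what `"hrp"` (vesicle density) or `"bulk"` (bulk area).
#' @return A ggplot object.
#' @export
plot_em_densities <- function(densities, what = c("hrp", "bulk")) {
  what <- match.arg(what)
  agg <- em_group_densities(densities)
  if (what == "hrp") {
    agg$mean <- agg$hrp_density_mean
    agg$sem <- agg$hrp_density_sem
    ylab <- expression("HRP(+) vesicles per " * mu * m^2)
  } else {
    agg$mean <- agg$bulk_area_mean
    agg$sem <- agg$bulk_area_sem
    ylab <- expression("Bulk endosome area per " * mu * m^2)
  }
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                    fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
}
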