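#' Plot the tactile-input-strength distribution
#'
#' Histogram of per-neuron mean tactile weights; the trained
#' body-constrained network shows a bimodal split into excitatory and
#' inhibitory neurons.
#'
#' @param profile an [rf_profile()] table.
#' @param bins histogram bins.
#' @return A ggplot object.
#' @export
plot_tactile_strength <- function(profile, bins = 40) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$tactile_strength,
                                        fill = .data$sign_class)) +
    ggplot2::geom_histogram(bins = bins, colour = "grey20", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean tactile weight", y = "neurons", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot visuo-proprioceptive overlap against preferred visual distance
#'
#' @param profile an [rf_profile()] table.
#' @return A ggplot object.
#' @export
plot_vp_overlap <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$preferred_visual_distance,
                               y = .data$vp_overlap,
                               colour = .data$sign_class)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "preferred visual distance (m)",
                  y = "visuo-proprioceptive overlap (r)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evoked tactile activity map in hand-centred coordinates
#'
#' @param map an [evoked_tactile_map()] table.
#' @param bin spatial bin width (m).
#' @return A ggplot object.
#' @export
plot_evoked_map <- function(map, bin = 0.05) {
  binned <- map |>
    dplyr::mutate(bx = round(.data$dx / bin) * bin,
                  by = round(.data$dy / bin) * bin) |>
    dplyr::group_by(.data$bx, .data$by) |>
    dplyr::summarise(evoked = mean(.data$evoked), .groups = "drop")
  ggplot2::ggplot(binned, ggplot2::aes(.data$bx, .data$by,
                                       fill = .data$evoked)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "stimulus x relative to hand (m)",
                  y = "stimulus y relative to hand (m)",
                  fill = "evoked\ntactile rate") +
    ggplot2::theme_minimal()
}

#' Plot simulated proprioceptive drift curves
#'
#' @param drift a [drift_experiment()] table.
#' @param as_pct plot drift as % of the disparity rather than in metres.
#' @return A ggplot object.
#' @export
plot_drift <- function(drift, as_pct = TRUE) {
  yvar <- if (as_pct) "drift_pct" else "drift_m"
  ggplot2::ggplot(drift,
                  ggplot2::aes(x = .data$offset, y = .data[[yvar]],
                               colour = factor(.data$touch_gain),
                               group = .data$touch_gain)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "visual offset from hand (m)",
                  y = if (as_pct) "proprioceptive drift (% of disparity)"
                      else "proprioceptive drift (m)",
                  colour = "tactile gain") +
    ggplot2::theme_minimal()
}

#' Plot training metrics across epochs
#'
#' @param fit a [pps_train()] result.
#' @return A ggplot object of reconstruction error (and overlap index at
#'   snapshot epochs) across training.
#' @export
plot_training <- function(fit) {
  m <- fit$metrics |>
    tidyr::pivot_longer(c("recon_error", "overlap_index"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(m, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pps_fit <- function(object, ...) plot_training(object)
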