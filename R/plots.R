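#' Plot methods for avspike results
#'
#' `autoplot()` methods draw the standard quick-look figures: smoothed
#' per-cue PSTHs, time-resolved decoding accuracy with its chance band,
#' and the all-pairs decoding matrix. [plot_msi_scatter()] draws the
#' per-neuron MSI comparison between two pairings and
#' [plot_selectivity_hist()] the selectivity histogram with significant
#' neurons filled.
#'
#' @param object an avspike result object.
#' @param ... unused.
#' @return A ggplot object.
#' @name avspike-plots
NULL

#' @rdname avspike-plots
#' @param what which PSTH series to draw: "smoothed_hz", "rate_hz" or "z".
#' @exportS3Method ggplot2::autoplot
autoplot.av_psth <- function(object, what = c("smoothed_hz", "rate_hz", "z"),
                             ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$bin_center, y = .data[[what]],
                               colour = .data$cue)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from cue onset (ms)",
                  y = if (what == "z") "rate (baseline z-score)"
                      else "rate (spikes/s)",
                  title = paste("neuron", object$neuron)) +
    ggplot2::theme_minimal()
}

#' @rdname avspike-plots
#' @exportS3Method ggplot2::autoplot
autoplot.av_decoding <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes(x = .data$center, y = .data$accuracy)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$null$lower, ymax = object$null$upper,
                      alpha = 0.15) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$accuracy - .data$sd,
                                      ymax = .data$accuracy + .data$sd),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "window center (ms)", y = "decoding accuracy",
                  title = paste(object$params$class_a, "vs",
                                object$params$class_b)) +
    ggplot2::theme_minimal()
}

#' @rdname avspike-plots
#' @exportS3Method ggplot2::autoplot
autoplot.av_decoding_matrix <- function(object, ...) {
  long <- tidy.av_decoding_matrix(object)
  cues <- rownames(object$accuracy)
  long$cue_a <- factor(long$cue_a, levels = cues)
  long$cue_b <- factor(long$cue_b, levels = rev(cues))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cue_a, y = .data$cue_b,
                                     fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$accuracy)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0.4, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("pairwise decoding, [%g, %g) ms",
                                  object$window[1], object$window[2])) +
    ggplot2::theme_minimal()
}

#' @rdname avspike-plots
#' @param msi_a,msi_b per-neuron MSI tibbles (from [msi()]) for the two
#'   pairings placed on the x and y axes.
#' @export
plot_msi_scatter <- function(msi_a, msi_b, ...) {
  d <- dplyr::inner_join(msi_a[c("neuron_id", "msi", "classification")],
                         msi_b[c("neuron_id", "msi", "classification")],
                         by = "neuron_id", suffix = c("_a", "_b"))
  d$significance <- dplyr::case_when(
    d$classification_a != "none" & d$classification_b != "none" ~ "both",
    d$classification_a != "none" ~ "x only",
    d$classification_b != "none" ~ "y only",
    TRUE ~ "neither")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$msi_a, y = .data$msi_b,
                                  colour = .data$significance)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste("MSI", msi_a$pairing[1]),
                  y = paste("MSI", msi_b$pairing[1])) +
    ggplot2::theme_minimal()
}

#' @rdname avspike-plots
#' @param si_tbl a selectivity tibble from [selectivity_index()].
#' @param binwidth histogram bin width on the SI axis.
#' @export
plot_selectivity_hist <- function(si_tbl, binwidth = 0.1, ...) {
  ggplot2::ggplot(si_tbl, ggplot2::aes(x = .data$si,
                                       fill = .data$significant)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25",
                                          `FALSE` = "white"),
                               na.value = "white") +
    ggplot2::labs(x = "selectivity index", y = "neurons") +
    ggplot2::theme_minimal()
}
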