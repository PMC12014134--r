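#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for avspike result objects
#'
#' `tidy()` returns the long per-element tibble of a result (PSTH bins,
#' decoding windows, correlation pairs, report categories); `glance()`
#' returns a one-row summary.
#'
#' @param x an avspike result object.
#' @param ... unused.
#' @return A tibble.
#' @name avspike-tidiers
NULL

#' @rdname avspike-tidiers
#' @exportS3Method generics::tidy
tidy.av_psth <- function(x, ...) x$bins

#' @rdname avspike-tidiers
#' @exportS3Method generics::glance
glance.av_psth <- function(x, ...) {
  tibble::tibble(neuron_id = x$neuron, n_cues = nrow(x$n_trials),
                 n_bins = nrow(x$bins) / nrow(x$n_trials),
                 bin_ms = x$config$bin_ms,
                 smooth_sd_ms = x$config$smooth_sd_ms,
                 any_degenerate_baseline = any(x$baseline$degenerate))
}

#' @rdname avspike-tidiers
#' @exportS3Method generics::tidy
tidy.av_decoding <- function(x, ...) x$windows

#' @rdname avspike-tidiers
#' @exportS3Method generics::glance
glance.av_decoding <- function(x, ...) {
  tibble::tibble(class_a = x$params$class_a, class_b = x$params$class_b,
                 n_neurons = x$params$n_neurons,
                 peak_accuracy = max(x$windows$accuracy),
                 peak_center_ms = x$windows$center[
                   which.max(x$windows$accuracy)],
                 null_mean = x$null$mean, null_lower = x$null$lower,
                 null_upper = x$null$upper,
                 resamples = x$params$resamples)
}

#' @rdname avspike-tidiers
#' @exportS3Method generics::tidy
tidy.av_decoding_matrix <- function(x, ...) {
  m <- x$accuracy
  out <- tidyr::expand_grid(cue_a = rownames(m), cue_b = colnames(m))
  out$accuracy <- as.vector(t(m))
  out
}

#' @rdname avspike-tidiers
#' @exportS3Method generics::tidy
tidy.av_correlation <- function(x, ...) x$data

#' @rdname avspike-tidiers
#' @exportS3Method generics::glance
glance.av_correlation <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, p_value = x$p_value, n = x$n,
                 conf_low = x$conf_low, conf_high = x$conf_high)
}

#' @rdname avspike-tidiers
#' @exportS3Method generics::tidy
tidy.av_comparison <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic,
                 p_value = x$p_value, normality_p = x$normality_p,
                 n = x$n, mean_a = x$mean_a, sd_a = x$sd_a,
                 mean_b = x$mean_b, sd_b = x$sd_b,
                 degenerate = x$degenerate)
}

#' @rdname avspike-tidiers
#' @exportS3Method generics::glance
glance.av_comparison <- tidy.av_comparison

#' @rdname avspike-tidiers
#' @exportS3Method generics::tidy
tidy.av_report <- function(x, ...) x$category_counts

#' @rdname avspike-tidiers
#' @exportS3Method generics::glance
glance.av_report <- function(x, ...) {
  msi_p <- if (is.null(x$msi_pairing_comparison)) NA_real_ else
    x$msi_pairing_comparison$p_value
  tibble::tibble(
    n_neurons = x$n_neurons,
    prop_visual_responsive = if (nrow(x$categories)) {
      mean(x$categories$visual | x$categories$category == "AV-only")
    } else 0,
    n_audiovisual = sum(x$category_counts$n[
      x$category_counts$category == "AV"]),
    msi_pairing_p = msi_p)
}
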