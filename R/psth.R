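#' Count spikes per trial in a half-open time window
#'
#' Windows are half-open `[start, end)` ms relative to cue onset, so a spike
#' exactly at `end` is not counted. Trials (and neurons) with no spikes are
#' kept with a count of zero.
#'
#' @param spikes spike table (`neuron_id`, `trial_id`, `spike_time_ms`).
#' @param trials trial selection: a trial table or a vector of trial ids.
#' @param window `c(start, end)` ms.
#' @param neurons optional character vector of neurons to count (default:
#'   all neurons present in `spikes`).
#' @return Tibble with one row per neuron x trial: `neuron_id`, `trial_id`,
#'   `n_spikes`, `rate_hz` (`n_spikes * 1000 / (end - start)`).
#' @export
#' @examples
#' spk <- tibble::tibble(neuron_id = "n1", trial_id = 1L, spike_time_ms = 5)
#' count_in_window(spk, 1:2, c(0, 150))
count_in_window <- function(spikes, trials, window, neurons = NULL) {
  check_window(window)
  trial_ids <- if (is.data.frame(trials)) trials$trial_id else trials
  if (length(trial_ids) == 0) {
    abort("empty trial selection", class = "avspike_validation_error")
  }
  neurons <- neurons %||% sort(unique(spikes$neuron_id))
  sel <- spikes[spikes$neuron_id %in% neurons &
                  spikes$trial_id %in% trial_ids &
                  spikes$spike_time_ms >= window[1] &
                  spikes$spike_time_ms < window[2], , drop = FALSE]
  grid <- tidyr::expand_grid(neuron_id = neurons,
                             trial_id = as.integer(trial_ids))
  counts <- dplyr::count(sel, .data$neuron_id, .data$trial_id,
                         name = "n_spikes")
  out <- dplyr::left_join(grid, counts, by = c("neuron_id", "trial_id"))
  out$n_spikes <- as.integer(dplyr::coalesce(out$n_spikes, 0L))
  out$rate_hz <- out$n_spikes * 1000 / diff(window)
  out
}

# Gaussian smoothing on an evenly spaced series; kernel truncated at
# +/- 3 sd and renormalised at the edges so mass is preserved
gaussian_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  h <- ceiling(3 * sd_bins)
  k <- dnorm(seq(-h, h), sd = sd_bins)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- max(1, i - h):min(n, i + h)
    w <- k[j - i + h + 1]
    sum(w * x[j]) / sum(w)
  }, numeric(1))
}

#' Peristimulus time histogram for one neuron
#'
#' Bins trial-aligned spike times (default 10 ms bins over the epoch),
#' averages across trials of each cue into a rate (spikes/s), smooths with
#' a Gaussian kernel (default sd 50 ms, truncated at 3 sd, edge
#' renormalised), and z-normalises the smoothed series by the mean and SD
#' of the raw binned rates inside the pre-cue baseline window (default the
#' 400 ms before cue onset). A zero baseline SD is flagged as degenerate
#' rather than returning infinite z-scores.
#'
#' @param spikes,trials session tables.
#' @param neuron neuron id (single string).
#' @param config `av_config` giving epoch, bin width, smoothing sd and
#'   baseline window.
#' @param cues cue subset (default: all cues present in `trials`).
#' @param correct_only restrict to correct trials (unmatched-cue trials,
#'   where correctness is undefined, are always kept).
#' @return An object of class `av_psth` with elements `bins` (long tibble:
#'   `cue`, `bin_start`, `bin_center`, `rate_hz`, `smoothed_hz`, `z`),
#'   `n_trials`, `baseline` (per-cue mean/SD and degeneracy flag) and
#'   `neuron`. `tidy()` returns the long bin tibble; `autoplot()` draws it.
#' @export
make_psth <- function(spikes, trials, neuron, config = session_config(),
                      cues = NULL, correct_only = TRUE) {
  stopifnot(length(neuron) == 1)
  cues <- cues %||% intersect(av_cues(), unique(trials$cue))
  ep <- config$epoch
  edges <- seq(ep[1], ep[2], by = config$bin_ms)
  nb <- length(edges) - 1
  spk <- spikes[spikes$neuron_id == neuron, , drop = FALSE]
  per_cue <- purrr::map(cues, function(cc) {
    tr <- usable_trials(trials, cc, correct_only)
    if (nrow(tr) == 0) {
      abort(paste0("no usable trials for cue ", cc),
            class = "avspike_validation_error")
    }
    t <- spk$spike_time_ms[spk$trial_id %in% tr$trial_id]
    t <- t[t >= ep[1] & t < ep[2]]
    idx <- floor((t - ep[1]) / config$bin_ms) + 1
    counts <- tabulate(idx, nbins = nb)
    rate <- counts * 1000 / (config$bin_ms * nrow(tr))
    smoothed <- gaussian_smooth(rate, config$smooth_sd_ms / config$bin_ms)
    bw <- config$baseline_window
    base_idx <- edges[-length(edges)] >= bw[1] & edges[-1] <= bw[2]
    # baseline statistics come from the raw binned rates: the smoothed
    # series would leak post-onset activity into late baseline bins and a
    # silent baseline must be detectably degenerate, not SD-inflated
    mu <- mean(rate[base_idx])
    sigma <- sd(rate[base_idx])
    degenerate <- !is.finite(sigma) || sigma == 0
    list(bins = tibble::tibble(
           cue = cc,
           bin_start = edges[-length(edges)],
           bin_center = edges[-length(edges)] + config$bin_ms / 2,
           rate_hz = rate, smoothed_hz = smoothed,
           z = if (degenerate) NA_real_ else (smoothed - mu) / sigma),
         n = nrow(tr),
         baseline = tibble::tibble(cue = cc, baseline_mean_hz = mu,
                                   baseline_sd_hz = sigma,
                                   degenerate = degenerate))
  })
  structure(list(
    bins = purrr::list_rbind(purrr::map(per_cue, "bins")),
    n_trials = tibble::tibble(cue = cues,
                              n = vapply(per_cue, function(x) x$n, 0L)),
    baseline = purrr::list_rbind(purrr::map(per_cue, "baseline")),
    neuron = neuron, config = config), class = "av_psth")
}

#' @export
print.av_psth <- function(x, ...) {
  cat(sprintf("<av_psth> neuron %s, %d bins x %d cues\n", x$neuron,
              nrow(x$bins) / nrow(x$n_trials), nrow(x$n_trials)))
  invisible(x)
}

#' Whole-epoch activity screen
#'
#' Units are retained for analysis only if their whole-epoch mean firing
#' rate reaches `min_rate_hz` (default 2 spikes/s).
#'
#' @param spikes,trials session tables.
#' @param config `av_config`.
#' @param min_rate_hz inclusion threshold, spikes/s.
#' @return Tibble: `neuron_id`, `mean_rate_hz`, `active`.
#' @export
active_neurons <- function(spikes, trials, config = session_config(),
                           min_rate_hz = config$min_rate_hz) {
  cc <- count_in_window(spikes, trials, config$epoch)
  out <- dplyr::summarise(dplyr::group_by(cc, .data$neuron_id),
                          mean_rate_hz = mean(.data$rate_hz), .groups = "drop")
  out$active <- out$mean_rate_hz >= min_rate_hz
  out
}

safe_signed_rank <- function(evoked, base, alternative = "greater") {
  d <- evoked - base
  if (all(d == 0)) return(list(p = NA_real_, degenerate = TRUE))
  p <- suppressWarnings(
    wilcox.test(evoked, base, paired = TRUE, alternative = alternative,
                exact = FALSE)$p.value)
  list(p = p, degenerate = FALSE)
}

#' Per-cue responsiveness screen
#'
#' For every neuron and cue, compares per-trial firing rates in the
#' responsiveness window (default 0-300 ms) against the pre-cue baseline
#' window with a paired Wilcoxon signed-rank test. A cue response counts as
#' responsive only if the baseline-subtracted evoked rate exceeds the
#' threshold (default 2 spikes/s) AND the signed-rank p-value is below
#' `alpha`. All-zero paired differences make the test undefined; such cues
#' are called non-responsive with a degeneracy flag.
#'
#' @param spikes,trials session tables.
#' @param config `av_config`.
#' @param neurons optional neuron subset.
#' @param correct_only use correct trials only (unmatched-cue trials kept).
#' @return Tibble, one row per neuron x cue: `neuron_id`, `cue`, `n_trials`,
#'   `evoked_hz` (baseline-subtracted), `p_value`, `responsive`,
#'   `degenerate`.
#' @seealso [categorize_neurons()] for the response-class taxonomy.
#' @export
classify_responsiveness <- function(spikes, trials,
                                    config = session_config(),
                                    neurons = NULL, correct_only = TRUE) {
  neurons <- neurons %||% sort(unique(spikes$neuron_id))
  cues <- intersect(av_cues(), unique(trials$cue))
  purrr::map_dfr(cues, function(cc) {
    tr <- usable_trials(trials, cc, correct_only)
    if (nrow(tr) < config$min_trials) {
      abort(sprintf("cue %s has %d usable trials; need >= %d", cc, nrow(tr),
                    config$min_trials),
            class = "avspike_insufficient_trials")
    }
    ev <- count_in_window(spikes, tr, config$responsiveness_window, neurons)
    ba <- count_in_window(spikes, tr, config$baseline_window, neurons)
    purrr::map_dfr(neurons, function(nn) {
      e <- ev$rate_hz[ev$neuron_id == nn]
      b <- ba$rate_hz[ba$neuron_id == nn]
      tst <- safe_signed_rank(e, b)
      evoked <- mean(e) - mean(b)
      tibble::tibble(
        neuron_id = nn, cue = cc, n_trials = nrow(tr), evoked_hz = evoked,
        p_value = tst$p,
        responsive = !tst$degenerate &&
          evoked > config$response_threshold_hz && tst$p < config$alpha,
        degenerate = tst$degenerate)
    })
  })
}

#' Response-class taxonomy from the responsiveness screen
#'
#' Assigns each neuron to auditory-only (`A`), visual-only (`V`), both
#' (`AV`), audiovisual-only (`AV-only`: responsive to a multisensory cue
#' but to neither unisensory modality) or `unresponsive`.
#'
#' @param responsiveness output of [classify_responsiveness()].
#' @return Tibble: `neuron_id`, `auditory`, `visual`, `multisensory`
#'   (logical, any responsive cue of that modality) and `category`.
#' @export
categorize_neurons <- function(responsiveness) {
  info <- av_cue_table()
  resp <- dplyr::left_join(responsiveness, info[c("cue", "modality")],
                           by = "cue")
  out <- dplyr::summarise(
    dplyr::group_by(resp, .data$neuron_id),
    auditory = any(.data$responsive[.data$modality == "auditory"]),
    visual = any(.data$responsive[.data$modality == "visual"]),
    multisensory = any(.data$responsive[.data$modality == "multisensory"]),
    .groups = "drop")
  out$category <- dplyr::case_when(
    out$auditory & out$visual ~ "AV",
    out$auditory ~ "A",
    out$visual ~ "V",
    out$multisensory ~ "AV-only",
    TRUE ~ "unresponsive")
  out
}
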