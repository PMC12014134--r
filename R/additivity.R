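#' Bootstrap additive-model test for multisensory responses
#'
#' Tests, per neuron, whether the observed mean multisensory response
#' departs from the additive prediction built from its unisensory
#' responses. Responses are per-trial baseline-subtracted rates in the
#' analysis window (the additive model applies to evoked rates, so the
#' baseline is not double-counted). Each bootstrap iteration resamples
#' `min(n_AV, pool)` auditory and visual trials (with replacement) and
#' records `coefficient * (mean auditory + mean visual)`; after `n_boot`
#' iterations the observed multisensory mean is expressed as a z-score,
#'
#' `z = (observed_mean - predicted_mean) / sqrt(predicted_SD^2 + observed_SE^2)`,
#'
#' whose denominator carries both the spread of the predicted distribution
#' and the sampling error of the observed mean, so that under additive
#' responses z is approximately standard normal. Neurons with
#' `z >= 1.96` are classified superadditive, `z <= -1.96` subadditive,
#' otherwise additive; a zero-variance prediction is flagged degenerate
#' rather than yielding an undefined z.
#'
#' @param spikes,trials session tables.
#' @param pairing a multisensory cue.
#' @param window analysis window, ms; default `config$analysis_window`.
#' @param config `av_config` (supplies `n_boot`, baseline window,
#'   `min_trials`).
#' @param seed optional seed for the bootstrap.
#' @param coefficient scaling applied to the predicted sum (default 1,
#'   the strictly additive model; see [scaling_coefficient()]).
#' @param n_boot bootstrap iterations.
#' @param correct_only restrict to correct trials.
#' @param neurons optional neuron subset.
#' @return Tibble, one row per neuron: sample sizes, `observed_mean`,
#'   `predicted_mean`, `predicted_sd`, `observed_se` (all spikes/s),
#'   `z`, `classification`, `degenerate`.
#' @export
additivity_test <- function(spikes, trials, pairing, window = NULL,
                            config = session_config(), seed = NULL,
                            coefficient = 1, n_boot = config$n_boot,
                            correct_only = TRUE, neurons = NULL) {
  window <- window %||% config$analysis_window
  check_window(window, config$epoch)
  check_number(coefficient, "coefficient", min = 0)
  info <- cue_info(pairing)
  if (info$modality != "multisensory") {
    abort(paste0(pairing, " is not a multisensory pairing"),
          class = "avspike_validation_error")
  }
  rates <- evoked_rates(spikes, trials, pairing, window, config,
                        correct_only, neurons)
  n_av <- length(rates$multi[[1]])
  with_seed_if(seed, purrr::map_dfr(names(rates$multi), function(nn) {
    av <- rates$multi[[nn]]
    aa <- rates$aud[[nn]]
    vv <- rates$vis[[nn]]
    da <- min(n_av, length(aa))
    dv <- min(n_av, length(vv))
    ma <- matrix(sample(aa, da * n_boot, replace = TRUE), nrow = da)
    mv <- matrix(sample(vv, dv * n_boot, replace = TRUE), nrow = dv)
    pred <- coefficient * (colMeans(ma) + colMeans(mv))
    pred_mean <- mean(pred)
    pred_sd <- sd(pred)
    obs_se <- sd(av) / sqrt(length(av))
    denom <- sqrt(pred_sd^2 + obs_se^2)
    # a zero-variance predicted distribution leaves the benchmark undefined
    # even if the observed mean itself is noisy
    degenerate <- !is.finite(denom) || denom == 0 || pred_sd == 0
    z <- if (degenerate) NA_real_ else (mean(av) - pred_mean) / denom
    classification <- if (degenerate) "degenerate"
      else if (z >= 1.96) "superadditive"
      else if (z <= -1.96) "subadditive" else "additive"
    tibble::tibble(
      neuron_id = nn, pairing = pairing, coefficient = coefficient,
      n_multi = length(av), n_auditory = length(aa), n_visual = length(vv),
      n_boot = as.integer(n_boot), observed_mean = mean(av),
      predicted_mean = pred_mean, predicted_sd = pred_sd,
      observed_se = obs_se, z = z, classification = classification,
      degenerate = degenerate)
  }))
}

#' Multisensory scaling coefficient
#'
#' Ratio of the observed mean multisensory evoked response to the sum of
#' the mean unisensory evoked responses (baseline-subtracted analysis
#' window rates): `c_hat = AV / (A + V)`. A value below 1 indicates
#' sub-additive combination. Undefined (flagged) when the summed
#' unisensory evoked response is not positive.
#'
#' @inheritParams additivity_test
#' @return Tibble, one row per neuron: component means (spikes/s),
#'   `c_hat`, `degenerate`.
#' @export
scaling_coefficient <- function(spikes, trials, pairing, window = NULL,
                                config = session_config(),
                                correct_only = TRUE, neurons = NULL) {
  window <- window %||% config$analysis_window
  check_window(window, config$epoch)
  info <- cue_info(pairing)
  if (info$modality != "multisensory") {
    abort(paste0(pairing, " is not a multisensory pairing"),
          class = "avspike_validation_error")
  }
  rates <- evoked_rates(spikes, trials, pairing, window, config,
                        correct_only, neurons)
  purrr::map_dfr(names(rates$multi), function(nn) {
    m_av <- mean(rates$multi[[nn]])
    m_a <- mean(rates$aud[[nn]])
    m_v <- mean(rates$vis[[nn]])
    degenerate <- (m_a + m_v) <= 0
    tibble::tibble(neuron_id = nn, pairing = pairing,
                   mean_multi = m_av, mean_auditory = m_a, mean_visual = m_v,
                   c_hat = if (degenerate) NA_real_ else m_av / (m_a + m_v),
                   degenerate = degenerate)
  })
}

# per-trial baseline-subtracted analysis-window rates for a pairing and its
# two unisensory components, as named lists of per-neuron vectors
evoked_rates <- function(spikes, trials, pairing, window, config,
                         correct_only, neurons = NULL) {
  info <- cue_info(pairing)
  cues <- c(multi = pairing, aud = info$auditory_component,
            vis = info$visual_component)
  neurons <- neurons %||% sort(unique(spikes$neuron_id))
  out <- purrr::map(cues, function(cc) {
    tr <- usable_trials(trials, cc, correct_only)
    if (nrow(tr) < config$min_trials) {
      abort(sprintf("cue %s has %d usable trials; need >= %d",
                    cc, nrow(tr), config$min_trials),
            class = "avspike_insufficient_trials")
    }
    win <- count_in_window(spikes, tr, window, neurons)
    base <- count_in_window(spikes, tr, config$baseline_window, neurons)
    ev <- win$rate_hz - base$rate_hz
    split(ev, win$neuron_id)[neurons]
  })
  names(out) <- names(cues)
  out
}
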