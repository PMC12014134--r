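#' Area under the ROC curve between two response samples
#'
#' Two estimators are provided. `exact_rank` is the deterministic
#' rank-based estimator: the fraction of cross pairs where an `a` sample
#' exceeds a `b` sample, counting ties as one half
#' (`(wins + 0.5 * ties) / (n_a * n_b)`). `discretized12` follows the
#' classical criterion-sweep construction: 12 linearly spaced criterion
#' levels spanning the pooled range (endpoints included); for each
#' criterion the fraction of `a` samples strictly exceeding it is plotted
#' against the fraction of `b` samples exceeding it, and the area is taken
#' by the trapezoidal rule with anchors (0,0) and (1,1). The two agree
#' exactly when the samples take at most 12 distinct values spanning the
#' criterion grid.
#'
#' @param a,b numeric response samples (e.g. per-trial spike counts), at
#'   least 2 values each.
#' @param method `"exact_rank"` (default) or `"discretized12"`.
#' @return auROC in \[0, 1\]. When all pooled values are identical the
#'   distributions are indistinguishable and 0.5 is returned with attribute
#'   `degenerate = TRUE`.
#' @export
#' @examples
#' compute_auroc(c(1, 2, 3), c(0, 1, 2))  # 7/9
compute_auroc <- function(a, b, method = c("exact_rank", "discretized12")) {
  method <- match.arg(method)
  if (!is.numeric(a) || !is.numeric(b) || length(a) < 2 || length(b) < 2 ||
      anyNA(a) || anyNA(b)) {
    abort("`a` and `b` must be numeric samples with >= 2 values each",
          class = "avspike_validation_error")
  }
  pool <- c(a, b)
  if (min(pool) == max(pool)) {
    return(structure(0.5, degenerate = TRUE))
  }
  if (method == "exact_rank") auroc_exact(a, b) else auroc_disc12(a, b)
}

auroc_exact <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
}

auroc_disc12 <- function(a, b, n_levels = 12L) {
  pool <- c(a, b)
  crit <- seq(min(pool), max(pool), length.out = n_levels)
  # strict exceedance; criteria descend so hit/false-alarm rates ascend
  x <- vapply(rev(crit), function(cc) mean(b > cc), numeric(1))
  y <- vapply(rev(crit), function(cc) mean(a > cc), numeric(1))
  x <- c(0, x, 1)
  y <- c(0, y, 1)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# permutation test of the ROC-based index: labels are randomly reassigned
# between the two samples; for the rank estimator the pooled ranks are
# fixed, so each permutation statistic is a sum over a random rank subset
auroc_perm_test <- function(a, b, n_perm,
                            method = c("exact_rank", "discretized12"),
                            alpha = 0.05) {
  method <- match.arg(method)
  obs <- compute_auroc(a, b, method)
  degenerate <- isTRUE(attr(obs, "degenerate"))
  obs <- as.numeric(obs)
  if (n_perm == 0 || degenerate) {
    return(list(auroc = obs, si = 2 * (obs - 0.5), p_value = NA_real_,
                significant = NA, degenerate = degenerate))
  }
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  if (method == "exact_rank") {
    r <- rank(c(a, b))
    offset <- na * (na + 1) / 2
    perm <- vapply(seq_len(n_perm), function(i) {
      (sum(r[sample.int(n, na)]) - offset) / (na * nb)
    }, numeric(1))
  } else {
    pool <- c(a, b)
    perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      auroc_disc12(pool[idx], pool[-idx])
    }, numeric(1))
  }
  p_hi <- (sum(perm >= obs) + 1) / (n_perm + 1)
  p_lo <- (sum(perm <= obs) + 1) / (n_perm + 1)
  p <- min(1, 2 * min(p_hi, p_lo))
  list(auroc = obs, si = 2 * (obs - 0.5), p_value = p,
       significant = p < alpha, degenerate = FALSE)
}

#' ROC-based cue-selectivity index with a permutation null
#'
#' For every neuron, spike counts in the analysis window (correct trials
#' only by default) are compared between two cues with [compute_auroc()];
#' the selectivity index is `SI = 2 * (auROC - 0.5)`, in \[-1, 1\], with
#' positive values indicating stronger responses to `cue_a`. Significance
#' comes from a two-tailed permutation test that reassigns trial labels
#' `n_perm` times; p-values use the add-one estimator `(r + 1) / (n + 1)`.
#'
#' @param spikes,trials session tables.
#' @param cue_a,cue_b the two cues to contrast (positive SI = prefers
#'   `cue_a`).
#' @param window analysis window, ms; default `config$analysis_window`.
#' @param config `av_config`.
#' @param seed optional seed for the permutation draw.
#' @param method auROC estimator, see [compute_auroc()].
#' @param n_perm permutation count (0 skips the test; p and significance
#'   are `NA`).
#' @param correct_only restrict to correct trials.
#' @param neurons optional neuron subset.
#' @return Tibble, one row per neuron: sample sizes, `auroc`, `si`,
#'   `p_value`, `significant`, `degenerate`, plus the window and method.
#' @export
selectivity_index <- function(spikes, trials, cue_a, cue_b, window = NULL,
                              config = session_config(), seed = NULL,
                              method = c("exact_rank", "discretized12"),
                              n_perm = config$n_perm, correct_only = TRUE,
                              neurons = NULL) {
  method <- match.arg(method)
  window <- window %||% config$analysis_window
  check_window(window, config$epoch)
  tr_a <- usable_trials(trials, cue_a, correct_only)
  tr_b <- usable_trials(trials, cue_b, correct_only)
  for (cc in list(list(cue_a, tr_a), list(cue_b, tr_b))) {
    if (nrow(cc[[2]]) < config$min_trials) {
      abort(sprintf("cue %s has %d usable trials; need >= %d",
                    cc[[1]], nrow(cc[[2]]), config$min_trials),
            class = "avspike_insufficient_trials")
    }
  }
  neurons <- neurons %||% sort(unique(spikes$neuron_id))
  ca <- count_in_window(spikes, tr_a, window, neurons)
  cb <- count_in_window(spikes, tr_b, window, neurons)
  with_seed_if(seed, purrr::map_dfr(neurons, function(nn) {
    res <- auroc_perm_test(ca$n_spikes[ca$neuron_id == nn],
                           cb$n_spikes[cb$neuron_id == nn],
                           n_perm, method, config$alpha)
    tibble::tibble(neuron_id = nn, cue_a = cue_a, cue_b = cue_b,
                   n_a = nrow(tr_a), n_b = nrow(tr_b),
                   window_start = window[1], window_end = window[2],
                   method = method, auroc = res$auroc, si = res$si,
                   n_perm = as.integer(n_perm), p_value = res$p_value,
                   significant = res$significant,
                   degenerate = res$degenerate)
  }))
}

#' Multisensory interactive index (MSI)
#'
#' Compares each neuron's multisensory response with its stronger
#' corresponding unisensory response using the same ROC machinery as
#' [selectivity_index()]: `MSI = 2 * (auROC - 0.5)`, positive when the
#' multisensory response is stronger (multisensory enhancement), negative
#' when weaker (inhibition). The stronger unisensory component is the one
#' with the higher mean analysis-window rate (ties go to auditory).
#' Neurons with a significant positive (negative) MSI are classified
#' `"enhanced"` (`"inhibited"`); otherwise `"none"`.
#'
#' @param spikes,trials session tables.
#' @param pairing a multisensory cue (`A3kVhz`, `A10kVvt`, `A10kVhz`,
#'   `A3kVvt`).
#' @inheritParams selectivity_index
#' @return Tibble, one row per neuron: `pairing`, `stronger_unisensory`
#'   (cue name), component mean rates, `auroc`, `msi`, `p_value`,
#'   `significant`, `classification`, sample sizes and window.
#' @export
msi <- function(spikes, trials, pairing, window = NULL,
                config = session_config(), seed = NULL,
                method = c("exact_rank", "discretized12"),
                n_perm = config$n_perm, correct_only = TRUE,
                neurons = NULL) {
  method <- match.arg(method)
  window <- window %||% config$analysis_window
  check_window(window, config$epoch)
  info <- cue_info(pairing)
  if (info$modality != "multisensory") {
    abort(paste0(pairing, " is not a multisensory pairing"),
          class = "avspike_validation_error")
  }
  cues <- c(pairing, info$auditory_component, info$visual_component)
  trs <- purrr::map(cues, usable_trials, trials = trials,
                    correct_only = correct_only)
  names(trs) <- cues
  for (cc in cues) {
    if (nrow(trs[[cc]]) < config$min_trials) {
      abort(sprintf("cue %s has %d usable trials; need >= %d",
                    cc, nrow(trs[[cc]]), config$min_trials),
            class = "avspike_insufficient_trials")
    }
  }
  neurons <- neurons %||% sort(unique(spikes$neuron_id))
  counts <- purrr::map(cues, function(cc) {
    count_in_window(spikes, trs[[cc]], window, neurons)
  })
  names(counts) <- cues
  with_seed_if(seed, purrr::map_dfr(neurons, function(nn) {
    multi <- counts[[pairing]]$n_spikes[counts[[pairing]]$neuron_id == nn]
    aud <- counts[[info$auditory_component]]
    vis <- counts[[info$visual_component]]
    aud <- aud$n_spikes[aud$neuron_id == nn]
    vis <- vis$n_spikes[vis$neuron_id == nn]
    rate <- 1000 / diff(window)
    stronger <- if (mean(aud) >= mean(vis)) info$auditory_component else
      info$visual_component
    uni <- if (stronger == info$auditory_component) aud else vis
    res <- auroc_perm_test(multi, uni, n_perm, method, config$alpha)
    classification <- if (is.na(res$significant) || !res$significant) "none"
      else if (res$si > 0) "enhanced" else "inhibited"
    tibble::tibble(
      neuron_id = nn, pairing = pairing, stronger_unisensory = stronger,
      mean_rate_multi_hz = mean(multi) * rate,
      mean_rate_auditory_hz = mean(aud) * rate,
      mean_rate_visual_hz = mean(vis) * rate,
      n_multi = length(multi), n_uni = length(uni),
      window_start = window[1], window_end = window[2], method = method,
      auroc = res$auroc, msi = res$si, n_perm = as.integer(n_perm),
      p_value = res$p_value, significant = res$significant,
      classification = classification, degenerate = res$degenerate)
  }))
}

#' MSI split by choice correctness
#'
#' Computes the MSI separately on correct-choice and incorrect-choice
#' trials of a pairing. Both the multisensory and the stronger-unisensory
#' samples are restricted to the corresponding choice subset; the stronger
#' unisensory component is determined once, from correct trials. Neurons
#' are only analysed when every involved cue has at least
#' `min_trials_choice` trials of each choice (default 9); otherwise all
#' rows are flagged `excluded` with the recorded reason.
#'
#' @param spikes,trials session tables.
#' @param pairing a multisensory target pairing (`A3kVhz` or `A10kVvt`;
#'   unmatched pairings have no defined correctness).
#' @inheritParams selectivity_index
#' @param min_trials minimum trials per choice per cue.
#' @return Tibble, two rows per neuron (`choice` = "correct"/"incorrect")
#'   with `msi`, `p_value`, sample sizes, `excluded` and `reason`.
#' @export
msi_by_choice <- function(spikes, trials, pairing, window = NULL,
                          config = session_config(), seed = NULL,
                          method = c("exact_rank", "discretized12"),
                          n_perm = 0,
                          min_trials = config$min_trials_choice,
                          neurons = NULL) {
  method <- match.arg(method)
  window <- window %||% config$analysis_window
  check_window(window, config$epoch)
  info <- cue_info(pairing)
  if (info$modality != "multisensory" || info$reward_side == "either") {
    abort("pairing must be a matched multisensory cue",
          class = "avspike_validation_error")
  }
  neurons <- neurons %||% sort(unique(spikes$neuron_id))
  # stronger unisensory from correct trials, held fixed across subsets
  aud_c <- usable_trials(trials, info$auditory_component, TRUE)
  vis_c <- usable_trials(trials, info$visual_component, TRUE)
  mean_by_neuron <- function(tr) {
    cc <- count_in_window(spikes, tr, window, neurons)
    setNames(tapply(cc$n_spikes, cc$neuron_id, mean)[neurons], neurons)
  }
  aud_mean <- mean_by_neuron(aud_c)
  vis_mean <- mean_by_neuron(vis_c)
  subsets <- list(correct = "yes", incorrect = "no")
  pools <- purrr::map(subsets, function(flag) {
    list(multi = trials[trials$cue == pairing & trials$correct == flag, ],
         aud = trials[trials$cue == info$auditory_component &
                        trials$correct == flag, ],
         vis = trials[trials$cue == info$visual_component &
                        trials$correct == flag, ])
  })
  n_tbl <- purrr::imap_dfr(pools, function(p, nm) {
    tibble::tibble(choice = nm, cue = c(pairing, info$auditory_component,
                                        info$visual_component),
                   n = c(nrow(p$multi), nrow(p$aud), nrow(p$vis)))
  })
  short <- n_tbl[n_tbl$n < min_trials, ]
  if (nrow(short) > 0) {
    reason <- paste0("below ", min_trials, " trials per choice: ",
                     paste(sprintf("%s %s (%d)", short$cue, short$choice,
                                   short$n), collapse = ", "))
    return(tidyr::expand_grid(neuron_id = neurons,
                              choice = names(subsets)) |>
             dplyr::mutate(pairing = pairing,
                           stronger_unisensory = NA_character_,
                           msi = NA_real_, p_value = NA_real_,
                           n_multi = NA_integer_, n_uni = NA_integer_,
                           excluded = TRUE, reason = reason))
  }
  with_seed_if(seed, purrr::map_dfr(names(subsets), function(nm) {
    p <- pools[[nm]]
    cm <- count_in_window(spikes, p$multi, window, neurons)
    ca <- count_in_window(spikes, p$aud, window, neurons)
    cv <- count_in_window(spikes, p$vis, window, neurons)
    purrr::map_dfr(neurons, function(nn) {
      stronger <- if (aud_mean[[nn]] >= vis_mean[[nn]])
        info$auditory_component else info$visual_component
      uni <- if (stronger == info$auditory_component)
        ca$n_spikes[ca$neuron_id == nn] else cv$n_spikes[cv$neuron_id == nn]
      multi <- cm$n_spikes[cm$neuron_id == nn]
      res <- auroc_perm_test(multi, uni, n_perm, method, config$alpha)
      tibble::tibble(neuron_id = nn, choice = nm, pairing = pairing,
                     stronger_unisensory = stronger, msi = res$si,
                     p_value = res$p_value, n_multi = length(multi),
                     n_uni = length(uni), excluded = FALSE,
                     reason = NA_character_)
    })
  }))
}

#' Relate the change in MSI to the change in selectivity
#'
#' For each neuron computes `x = MSI(preferred pairing) - MSI(non-preferred
#' pairing)` and `y = multisensory selectivity - auditory selectivity`
#' (multisensory selectivity contrasts the two matched pairings; auditory
#' selectivity contrasts their tones, both signed toward the preferred
#' pairing), then the Pearson correlation between x and y across neurons.
#'
#' @param spikes,trials session tables.
#' @param pairing_pref,pairing_nonpref matched pairings defining the
#'   contrast.
#' @inheritParams selectivity_index
#' @return An object of class `av_correlation`: the per-neuron tibble
#'   (`data`), `estimate` (Pearson r), `p_value`, `n`. `tidy()` returns the
#'   per-neuron pairs, `glance()` the correlation summary.
#' @export
delta_msi_selectivity <- function(spikes, trials,
                                  pairing_pref = "A10kVvt",
                                  pairing_nonpref = "A3kVhz",
                                  window = NULL,
                                  config = session_config(), seed = NULL,
                                  method = c("exact_rank", "discretized12"),
                                  neurons = NULL) {
  method <- match.arg(method)
  pref_info <- cue_info(pairing_pref)
  nonpref_info <- cue_info(pairing_nonpref)
  m_pref <- msi(spikes, trials, pairing_pref, window, config, seed = seed,
                method = method, n_perm = 0, neurons = neurons)
  m_non <- msi(spikes, trials, pairing_nonpref, window, config, seed = seed,
               method = method, n_perm = 0, neurons = neurons)
  si_multi <- selectivity_index(spikes, trials, pairing_pref, pairing_nonpref,
                                window, config, seed = seed, method = method,
                                n_perm = 0, neurons = neurons)
  si_aud <- selectivity_index(spikes, trials, pref_info$auditory_component,
                              nonpref_info$auditory_component,
                              window, config, seed = seed, method = method,
                              n_perm = 0, neurons = neurons)
  data <- tibble::tibble(
    neuron_id = m_pref$neuron_id,
    delta_msi = m_pref$msi - m_non$msi,
    delta_si = si_multi$si - si_aud$si)
  data <- data[stats::complete.cases(data), ]
  if (nrow(data) < 3) {
    abort("need at least 3 neurons with all four indices defined",
          class = "avspike_validation_error")
  }
  ct <- cor.test(data$delta_msi, data$delta_si, method = "pearson")
  structure(list(data = data, estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = nrow(data),
                 conf_low = ct$conf.int[1], conf_high = ct$conf.int[2]),
            class = "av_correlation")
}

#' @export
print.av_correlation <- function(x, ...) {
  cat(sprintf("<av_correlation> Pearson r = %.3f (p = %.3g, n = %d)\n",
              x$estimate, x$p_value, x$n))
  invisible(x)
}
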