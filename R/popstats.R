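#' Behavioural correct rate per cue
#'
#' `100 * correct trials / total trials`, per cue. Unmatched multisensory
#' cues (where either port is rewarded and correctness is undefined) are
#' excluded unless `include_unmatched = TRUE`, in which case they appear
#' with `NA` rates.
#'
#' @param trials trial table.
#' @param cue optional single cue; errors if it has no trials.
#' @param include_unmatched keep unmatched cues (with `NA` correct rate).
#' @return Tibble: `cue`, `n_trials`, `n_correct`, `correct_rate` (percent).
#' @export
#' @examples
#' tr <- tibble::tibble(trial_id = 1:10, cue = "A3k",
#'                      choice = "right",
#'                      correct = rep(c("yes", "no"), c(8, 2)),
#'                      reaction_time_ms = 300)
#' correct_rate(tr)
correct_rate <- function(trials, cue = NULL, include_unmatched = FALSE) {
  tt <- trials
  if (!is.null(cue)) {
    tt <- tt[tt$cue %in% cue, , drop = FALSE]
    if (nrow(tt) == 0) {
      abort(paste0("no trials for cue ", paste(cue, collapse = ", ")),
            class = "avspike_validation_error")
    }
  }
  out <- dplyr::summarise(
    dplyr::group_by(tt, cue = .data$cue),
    n_trials = dplyr::n(),
    n_correct = sum(.data$correct == "yes"),
    undefined = all(.data$correct == "either"),
    .groups = "drop")
  out$correct_rate <- ifelse(out$undefined, NA_real_,
                             100 * out$n_correct / out$n_trials)
  if (!include_unmatched) out <- out[!out$undefined, , drop = FALSE]
  out$undefined <- NULL
  out
}

#' Reaction-time summary by modality
#'
#' Mean and SD of reaction time over correct trials, per cue modality,
#' with a cumulative-frequency table attached (attribute `"cumulative"`)
#' for plotting. Modalities with no correct trials are kept as rows with
#' `NA` summaries and `missing = TRUE`.
#'
#' @param trials trial table.
#' @return Tibble: `modality`, `n_correct`, `mean_rt_ms`, `sd_rt_ms`,
#'   `missing`.
#' @export
reaction_time_summary <- function(trials) {
  info <- av_cue_table()
  tt <- dplyr::left_join(trials, info[c("cue", "modality")], by = "cue")
  tt <- tt[tt$correct == "yes" & !is.na(tt$reaction_time_ms), , drop = FALSE]
  mods <- c("auditory", "visual", "multisensory")
  out <- purrr::map_dfr(mods, function(m) {
    rt <- tt$reaction_time_ms[tt$modality == m]
    tibble::tibble(modality = m, n_correct = length(rt),
                   mean_rt_ms = if (length(rt)) mean(rt) else NA_real_,
                   sd_rt_ms = if (length(rt) > 1) sd(rt) else
                     if (length(rt) == 1) 0 else NA_real_,
                   missing = length(rt) == 0)
  })
  cum <- dplyr::arrange(
    dplyr::mutate(
      dplyr::group_by(tt[c("modality", "reaction_time_ms")], .data$modality),
      cum_freq = dplyr::cume_dist(.data$reaction_time_ms)),
    .data$modality, .data$reaction_time_ms)
  attr(out, "cumulative") <- dplyr::ungroup(cum)
  out
}

#' Normality-gated paired comparison
#'
#' Runs a Shapiro-Wilk test on the paired differences; if they look normal
#' (p >= alpha) the paired t-test is used, otherwise the Wilcoxon
#' signed-rank test. Both the gate p-value and the chosen test are
#' reported. All-zero differences make both tests undefined; the result is
#' flagged degenerate with "no difference".
#'
#' @param a,b paired numeric vectors of equal length >= 3.
#' @param alpha normality-gate level.
#' @return An object of class `av_comparison` (list with `test`,
#'   `statistic`, `p_value`, `normality_p`, `n`, per-group mean/SD,
#'   `degenerate`). `tidy()`/`glance()` return one-row tibbles.
#' @export
compare_paired <- function(a, b, alpha = 0.05) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b) ||
      length(a) < 3) {
    abort("`a` and `b` must be equal-length numeric vectors, n >= 3",
          class = "avspike_validation_error")
  }
  d <- a - b
  base <- list(n = length(a), mean_a = mean(a), sd_a = sd(a),
               mean_b = mean(b), sd_b = sd(b))
  if (all(d == 0)) {
    return(structure(c(base, list(test = "none", statistic = NA_real_,
                                  p_value = NA_real_,
                                  normality_p = NA_real_,
                                  degenerate = TRUE)),
                     class = "av_comparison"))
  }
  sw <- tryCatch(shapiro.test(d)$p.value, error = function(e) NA_real_)
  use_t <- !is.na(sw) && sw >= alpha
  if (use_t) {
    ht <- t.test(a, b, paired = TRUE)
    test <- "paired-t"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
    test <- "signed-rank"
  }
  structure(c(base, list(test = test, statistic = unname(ht$statistic),
                         p_value = ht$p.value, normality_p = sw,
                         degenerate = FALSE)),
            class = "av_comparison")
}

#' @export
print.av_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("<av_comparison> no difference (all paired differences zero)\n")
  } else {
    cat(sprintf(
      "<av_comparison> %s: statistic = %.4g, p = %.3g (normality p = %.3g, n = %d)\n",
      x$test, x$statistic, x$p_value, x$normality_p, x$n))
  }
  invisible(x)
}

#' Chi-square test for two proportions
#'
#' Pearson chi-square on the 2x2 table of successes/failures, without
#' continuity correction by default. Expected cell counts below 1 are
#' flagged. Degenerate margins (all successes or all failures) yield an
#' undefined statistic with a flag.
#'
#' @param k1,n1,k2,n2 successes and totals of the two groups.
#' @param correct apply the Yates continuity correction.
#' @return Tibble: `chi_square`, `df`, `p_value`, `p1`, `p2`,
#'   `low_expected`, `degenerate`.
#' @export
#' @examples
#' proportion_test(90, 100, 10, 100)  # chi-square = 128
proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  for (v in list(c(k1, n1), c(k2, n2))) {
    if (v[2] <= 0 || v[1] < 0 || v[1] > v[2]) {
      abort("need 0 <= k <= n and n > 0 for both groups",
            class = "avspike_validation_error")
    }
  }
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  degenerate <- any(colSums(tab) == 0)
  if (degenerate) {
    return(tibble::tibble(chi_square = NA_real_, df = 1L, p_value = NA_real_,
                          p1 = k1 / n1, p2 = k2 / n2, low_expected = NA,
                          degenerate = TRUE))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble::tibble(chi_square = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, p1 = k1 / n1, p2 = k2 / n2,
                 low_expected = any(expected < 1), degenerate = FALSE)
}

#' Population-level summary of a session
#'
#' Composes the single-neuron analyses into the study-style population
#' report: response-class proportions, counts of significantly selective
#' neurons by preferred cue for the auditory, visual and multisensory
#' contrasts, enhancement/inhibition counts and mean MSI per matched
#' pairing, the paired MSI comparison across pairings, the comparison of
#' mean absolute selectivity between auditory and multisensory contrasts
#' over audiovisual neurons, and the behavioural summaries.
#'
#' @param spikes,trials session tables.
#' @param config `av_config`.
#' @param seed optional seed (permutations).
#' @param n_perm permutation count for the per-neuron significance calls.
#' @param contrasts named list of the three selectivity contrasts; each a
#'   `c(cue_a, cue_b)` pair with positive SI pointing at `cue_a`.
#' @param pairings matched pairings to analyse for MSI.
#' @return An object of class `av_report`: tibbles `categories`,
#'   `category_counts`, `selectivity`, `selectivity_counts`, `msi`,
#'   `msi_counts`, comparisons `msi_pairing_comparison` and
#'   `abs_si_comparison` (`av_comparison` or `NULL`), `behavior` (correct
#'   rates, reaction times), `n_neurons`.
#' @export
population_report <- function(spikes, trials, config = session_config(),
                              seed = NULL, n_perm = config$n_perm,
                              contrasts = list(
                                auditory = c("A10k", "A3k"),
                                visual = c("Vvt", "Vhz"),
                                multisensory = c("A10kVvt", "A3kVhz")),
                              pairings = c("A10kVvt", "A3kVhz")) {
  neurons <- sort(unique(spikes$neuron_id))
  n_neurons <- length(neurons)
  empty <- n_neurons == 0
  if (empty) {
    cat_counts <- tibble::tibble(
      category = c("A", "V", "AV", "AV-only", "unresponsive"),
      n = 0L, proportion = 0)
    return(structure(list(categories = tibble::tibble(),
                          category_counts = cat_counts,
                          selectivity = tibble::tibble(),
                          selectivity_counts = tibble::tibble(),
                          msi = tibble::tibble(),
                          msi_counts = tibble::tibble(),
                          msi_pairing_comparison = NULL,
                          abs_si_comparison = NULL,
                          behavior = list(
                            correct_rate = correct_rate(trials),
                            reaction_time = reaction_time_summary(trials)),
                          n_neurons = 0L),
                     class = "av_report"))
  }
  seed <- seed %||% config$seed
  resp <- classify_responsiveness(spikes, trials, config)
  categories <- categorize_neurons(resp)
  cat_counts <- dplyr::count(categories, category = .data$category,
                             name = "n")
  cat_counts <- tidyr::complete(
    cat_counts,
    category = c("A", "V", "AV", "AV-only", "unresponsive"),
    fill = list(n = 0L))
  cat_counts$proportion <- cat_counts$n / n_neurons

  sel <- purrr::imap_dfr(contrasts, function(cs, nm) {
    out <- selectivity_index(spikes, trials, cs[1], cs[2], config = config,
                             seed = seed, n_perm = n_perm)
    out$contrast <- nm
    out
  })
  sel_counts <- dplyr::summarise(
    dplyr::group_by(sel, contrast = .data$contrast),
    n = dplyr::n(),
    n_significant = sum(.data$significant, na.rm = TRUE),
    n_prefer_a = sum(.data$significant & .data$si > 0, na.rm = TRUE),
    n_prefer_b = sum(.data$significant & .data$si < 0, na.rm = TRUE),
    mean_abs_si = mean(abs(.data$si)), .groups = "drop")

  msi_tbl <- purrr::map_dfr(pairings, function(p) {
    msi(spikes, trials, p, config = config, seed = seed, n_perm = n_perm)
  })
  av_ids <- categories$neuron_id[categories$category == "AV"]
  msi_counts <- dplyr::summarise(
    dplyr::group_by(msi_tbl, pairing = .data$pairing),
    n = dplyr::n(),
    n_enhanced = sum(.data$classification == "enhanced"),
    n_inhibited = sum(.data$classification == "inhibited"),
    mean_msi = mean(.data$msi),
    n_enhanced_av = sum(.data$classification == "enhanced" &
                          .data$neuron_id %in% av_ids),
    n_inhibited_av = sum(.data$classification == "inhibited" &
                           .data$neuron_id %in% av_ids),
    mean_msi_av = if (any(.data$neuron_id %in% av_ids))
      mean(.data$msi[.data$neuron_id %in% av_ids]) else NA_real_,
    .groups = "drop")

  msi_cmp <- NULL
  if (length(pairings) == 2 && length(av_ids) >= 3) {
    wide <- tidyr::pivot_wider(
      msi_tbl[msi_tbl$neuron_id %in% av_ids, c("neuron_id", "pairing", "msi")],
      names_from = "pairing", values_from = "msi")
    msi_cmp <- compare_paired(wide[[pairings[1]]], wide[[pairings[2]]])
  }
  si_cmp <- NULL
  sel_av <- sel[sel$neuron_id %in% av_ids, ]
  if (length(av_ids) >= 3 &&
      all(c("auditory", "multisensory") %in% sel_av$contrast)) {
    wide_si <- tidyr::pivot_wider(
      sel_av[c("neuron_id", "contrast", "si")],
      names_from = "contrast", values_from = "si")
    si_cmp <- compare_paired(abs(wide_si$multisensory), abs(wide_si$auditory))
  }
  structure(list(categories = categories, category_counts = cat_counts,
                 selectivity = sel, selectivity_counts = sel_counts,
                 msi = msi_tbl, msi_counts = msi_counts,
                 msi_pairing_comparison = msi_cmp,
                 abs_si_comparison = si_cmp,
                 behavior = list(
                   correct_rate = correct_rate(trials),
                   reaction_time = reaction_time_summary(trials)),
                 n_neurons = n_neurons),
            class = "av_report")
}

#' @export
print.av_report <- function(x, ...) {
  cat(sprintf("<av_report> %d neurons\n", x$n_neurons))
  cat("response classes:\n")
  print(x$category_counts, n = 5)
  if (nrow(x$selectivity_counts)) {
    cat("selectivity:\n")
    print(x$selectivity_counts)
  }
  if (nrow(x$msi_counts)) {
    cat("multisensory interaction:\n")
    print(x$msi_counts)
  }
  invisible(x)
}
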