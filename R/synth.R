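#' Behavioural parameters for the synthetic session generator
#'
#' Describes the animal side of a synthetic session: per-modality
#' correct-choice probabilities and shifted-lognormal reaction-time
#' distributions. Defaults emulate a well-trained animal: better and faster
#' on multisensory trials (90% correct, mean RT 367 ms) than on auditory
#' (82%, 426 ms) or visual (82%, 417 ms) trials.
#'
#' @param p_correct named vector of correct-choice probabilities for
#'   `auditory`, `visual` and `multisensory` cues.
#' @param rt_mean_ms named vector of target mean reaction times (ms).
#' @param rt_sdlog lognormal shape parameter of the reaction-time spread.
#' @param rt_shift_ms non-decision shift of the reaction time (ms).
#' @param p_left_unmatched probability of a left choice on unmatched-cue
#'   trials (either port is rewarded there).
#' @return An object of class `av_behavior_spec`.
#' @export
behavior_spec <- function(p_correct = c(auditory = 0.82, visual = 0.82,
                                        multisensory = 0.90),
                          rt_mean_ms = c(auditory = 426, visual = 417,
                                         multisensory = 367),
                          rt_sdlog = 0.35,
                          rt_shift_ms = 150,
                          p_left_unmatched = 0.5) {
  mods <- c("auditory", "visual", "multisensory")
  stopifnot(all(mods %in% names(p_correct)), all(mods %in% names(rt_mean_ms)))
  if (any(p_correct < 0 | p_correct > 1) ||
      p_left_unmatched < 0 || p_left_unmatched > 1) {
    abort("probabilities must lie in [0, 1]", class = "avspike_validation_error")
  }
  if (any(rt_mean_ms <= rt_shift_ms)) {
    abort("rt_mean_ms must exceed rt_shift_ms", class = "avspike_validation_error")
  }
  structure(list(p_correct = p_correct[mods], rt_mean_ms = rt_mean_ms[mods],
                 rt_sdlog = rt_sdlog, rt_shift_ms = rt_shift_ms,
                 p_left_unmatched = p_left_unmatched),
            class = "av_behavior_spec")
}

#' Population parameters for the synthetic session generator
#'
#' Describes the neural side of a synthetic session. Each neuron draws a
#' response class from `weights` (auditory-only, visual-only, audiovisual,
#' audiovisual-only, unresponsive), a gamma-distributed baseline rate, and
#' gamma-distributed evoked gains for its responsive cues. A per-neuron
#' preference coin (`pref_bias`) decides which tone gets the preferred-gain
#' mean; visual preference follows the auditory preference with probability
#' `congruence`. Multisensory trials combine the evoked rates additively and
#' scale the sum by a pairing-specific interaction factor `c` drawn from
#' `interaction` (`c = 1` additive, `> 1` enhancement, `< 1` suppression);
#' on incorrect-choice trials `c - 1` is shrunk by `incorrect_shrink`.
#'
#' @param n_neurons number of neurons.
#' @param trials_per_cue trials generated per cue.
#' @param weights mixture weights over response classes; must sum to 1.
#' @param baseline_mean_hz,baseline_shape gamma parameters of the baseline
#'   rate (spikes/s).
#' @param gain_means named vector of mean evoked gains (spikes/s):
#'   `aud_pref`, `aud_nonpref`, `vis_pref`, `vis_nonpref`.
#' @param gain_shape gamma shape of all gain draws.
#' @param vis_nonpref_zero_prob probability the non-preferred visual gain is
#'   exactly zero (many task-engaged neurons respond to a single light bar).
#' @param pref_bias probability a neuron's preferred tone is `pref_aud_cue`.
#' @param congruence probability the preferred light bar is the one paired
#'   with the preferred tone during training.
#' @param pref_aud_cue,pref_vis_cue the trained contralateral cue pair.
#' @param interaction named list over the four pairings; each element
#'   `c(mean, sd)` of the per-neuron interaction factor (truncated at 0).
#' @param latency_ms named vector of response onset latencies (ms) for
#'   `auditory` and `visual` components.
#' @param duration_ms evoked-response duration (ms).
#' @param incorrect_shrink factor in \[0, 1\] multiplying `c - 1` on
#'   incorrect-choice multisensory trials (0 removes the interaction, 1
#'   leaves it untouched).
#' @param include_unmatched also generate the two unmatched pairings.
#' @param seed optional integer seed used by [generate_session()].
#' @return An object of class `av_population_spec`.
#' @export
population_spec <- function(n_neurons = 200,
                            trials_per_cue = 40,
                            weights = c(auditory = 0.33, visual = 0.08,
                                        audiovisual = 0.27,
                                        audiovisual_only = 0.01,
                                        unresponsive = 0.31),
                            baseline_mean_hz = 5,
                            baseline_shape = 2,
                            gain_means = c(aud_pref = 8, aud_nonpref = 2.5,
                                           vis_pref = 6, vis_nonpref = 0.5),
                            gain_shape = 3,
                            vis_nonpref_zero_prob = 0.8,
                            pref_bias = 0.85,
                            congruence = 0.85,
                            pref_aud_cue = "A10k",
                            pref_vis_cue = "Vvt",
                            interaction = list(
                              A3kVhz = c(mean = 1, sd = 0.1),
                              A10kVvt = c(mean = 1.5, sd = 0.25),
                              A10kVhz = c(mean = 1, sd = 0.1),
                              A3kVvt = c(mean = 1, sd = 0.1)),
                            latency_ms = c(auditory = 20, visual = 50),
                            duration_ms = 130,
                            incorrect_shrink = 0.5,
                            include_unmatched = FALSE,
                            seed = NULL) {
  classes <- c("auditory", "visual", "audiovisual", "audiovisual_only",
               "unresponsive")
  stopifnot(all(classes %in% names(weights)))
  weights <- weights[classes]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("class weights must be non-negative and sum to 1",
          class = "avspike_validation_error")
  }
  check_number(n_neurons, "n_neurons", min = 1)
  check_number(trials_per_cue, "trials_per_cue", min = 1)
  check_number(baseline_mean_hz, "baseline_mean_hz", min = 0)
  check_number(duration_ms, "duration_ms", min = 1e-9)
  if (incorrect_shrink < 0 || incorrect_shrink > 1) {
    abort("incorrect_shrink must lie in [0, 1]",
          class = "avspike_validation_error")
  }
  if (any(gain_means < 0)) {
    abort("gain means must be >= 0", class = "avspike_validation_error")
  }
  pairings <- av_cues("multisensory")
  stopifnot(all(pairings %in% names(interaction)))
  stopifnot(pref_aud_cue %in% av_cues("auditory"),
            pref_vis_cue %in% av_cues("visual"))
  structure(list(n_neurons = as.integer(n_neurons),
                 trials_per_cue = as.integer(trials_per_cue),
                 weights = weights,
                 baseline_mean_hz = baseline_mean_hz,
                 baseline_shape = baseline_shape,
                 gain_means = gain_means, gain_shape = gain_shape,
                 vis_nonpref_zero_prob = vis_nonpref_zero_prob,
                 pref_bias = pref_bias, congruence = congruence,
                 pref_aud_cue = pref_aud_cue, pref_vis_cue = pref_vis_cue,
                 interaction = interaction[pairings],
                 latency_ms = latency_ms, duration_ms = duration_ms,
                 incorrect_shrink = incorrect_shrink,
                 include_unmatched = isTRUE(include_unmatched),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "av_population_spec")
}

rgamma_mean <- function(n, mean, shape) {
  if (mean <= 0) return(rep(0, n))
  rgamma(n, shape = shape, rate = shape / mean)
}

# draw per-neuron ground-truth parameters from a population spec
draw_neuron_truth <- function(pop) {
  n <- pop$n_neurons
  class <- sample(names(pop$weights), n, replace = TRUE, prob = pop$weights)
  aud_cues <- av_cues("auditory")
  vis_cues <- av_cues("visual")
  pref_aud <- ifelse(runif(n) < pop$pref_bias, pop$pref_aud_cue,
                     setdiff(aud_cues, pop$pref_aud_cue))
  aligned_vis <- ifelse(pref_aud == pop$pref_aud_cue, pop$pref_vis_cue,
                        setdiff(vis_cues, pop$pref_vis_cue))
  pref_vis <- ifelse(runif(n) < pop$congruence, aligned_vis,
                     ifelse(aligned_vis == vis_cues[1], vis_cues[2], vis_cues[1]))
  gm <- pop$gain_means
  gains <- matrix(0, n, 4, dimnames = list(NULL, c(aud_cues, vis_cues)))
  has_aud <- class %in% c("auditory", "audiovisual")
  has_vis <- class %in% c("visual", "audiovisual")
  for (cue in aud_cues) {
    m <- ifelse(pref_aud == cue, gm[["aud_pref"]], gm[["aud_nonpref"]])
    gains[, cue] <- ifelse(has_aud, rgamma_mean(n, 1, pop$gain_shape) * m, 0)
  }
  for (cue in vis_cues) {
    pref <- pref_vis == cue
    m <- ifelse(pref, gm[["vis_pref"]], gm[["vis_nonpref"]])
    zero <- !pref & runif(n) < pop$vis_nonpref_zero_prob
    gains[, cue] <- ifelse(has_vis & !zero,
                           rgamma_mean(n, 1, pop$gain_shape) * m, 0)
  }
  # audiovisual-only neurons: unisensory gains too weak to pass the
  # responsiveness screen, combination lifted by a strong interaction factor
  av_only <- class == "audiovisual_only"
  for (cue in c(aud_cues, vis_cues)) {
    gains[av_only, cue] <- rgamma_mean(sum(av_only), 0.8, pop$gain_shape)
  }
  cmat <- vapply(names(pop$interaction), function(p) {
    pars <- pop$interaction[[p]]
    pmax(0, rnorm(n, pars[["mean"]], pars[["sd"]]))
  }, numeric(n))
  if (is.null(dim(cmat))) cmat <- matrix(cmat, nrow = n)
  colnames(cmat) <- names(pop$interaction)
  cmat[av_only, ] <- 4
  tibble::tibble(
    neuron_id = sprintf("n%03d", seq_len(n)),
    class = class,
    baseline_hz = rgamma_mean(n, pop$baseline_mean_hz, pop$baseline_shape),
    pref_aud = pref_aud, pref_vis = pref_vis,
    gain_A3k = gains[, "A3k"], gain_A10k = gains[, "A10k"],
    gain_Vhz = gains[, "Vhz"], gain_Vvt = gains[, "Vvt"],
    c_A3kVhz = cmat[, "A3kVhz"], c_A10kVvt = cmat[, "A10kVvt"],
    c_A10kVhz = cmat[, "A10kVhz"], c_A3kVvt = cmat[, "A3kVvt"],
    auditory_latency_ms = pop$latency_ms[["auditory"]],
    visual_latency_ms = pop$latency_ms[["visual"]],
    response_duration_ms = pop$duration_ms,
    incorrect_shrink = pop$incorrect_shrink
  )
}

draw_trials <- function(pop, behavior) {
  cues <- c(av_cues(c("auditory", "visual")), "A3kVhz", "A10kVvt")
  if (pop$include_unmatched) cues <- c(cues, "A10kVhz", "A3kVvt")
  info <- cue_info(cues)
  per_cue <- pop$trials_per_cue
  n <- length(cues) * per_cue
  cue <- rep(cues, each = per_cue)
  ci <- info[rep(seq_along(cues), each = per_cue), ]
  modality <- ci$modality
  side <- ci$reward_side
  unmatched <- side == "either"
  p_corr <- behavior$p_correct[modality]
  is_corr <- runif(n) < p_corr
  other <- ifelse(side == "left", "right", "left")
  choice <- ifelse(is_corr, side, other)
  choice[unmatched] <- ifelse(runif(sum(unmatched)) < behavior$p_left_unmatched,
                              "left", "right")
  correct <- ifelse(is_corr, "yes", "no")
  correct[unmatched] <- "either"
  meanlog <- log(behavior$rt_mean_ms[modality] - behavior$rt_shift_ms) -
    behavior$rt_sdlog^2 / 2
  rt <- behavior$rt_shift_ms + rlnorm(n, meanlog, behavior$rt_sdlog)
  ord <- sample.int(n)
  tibble::tibble(trial_id = seq_len(n),
                 cue = cue[ord], choice = unname(choice[ord]),
                 correct = unname(correct[ord]),
                 reaction_time_ms = unname(round(rt[ord], 1)))
}

# piecewise-constant-rate Poisson spikes for one neuron over all trials:
# baseline over the whole epoch plus, per active modality, an evoked segment
# from latency to latency + duration; multisensory trials scale the summed
# evoked rates by the pairing's interaction factor (shrunk toward 1 on
# incorrect choices)
simulate_neuron_spikes <- function(nrn, trials, config) {
  ep <- config$epoch
  info <- cue_info(trials$cue)
  n <- nrow(trials)
  c_cols <- paste0("c_", trials$cue)
  c_pair <- rep(1, n)
  multi <- info$modality == "multisensory"
  c_pair[multi] <- vapply(which(multi),
                          function(i) nrn[[c_cols[i]]], numeric(1))
  wrong <- trials$correct == "no"
  c_eff <- ifelse(multi & wrong, 1 + nrn$incorrect_shrink * (c_pair - 1), c_pair)

  emit <- function(rate_hz, t0, t1) {
    lam <- rate_hz * (t1 - t0) / 1000
    counts <- rpois(n, lam)
    tot <- sum(counts)
    if (tot == 0) return(NULL)
    tibble::tibble(trial_id = rep(trials$trial_id, counts),
                   spike_time_ms = runif(tot, t0, t1))
  }
  base <- emit(rep(nrn$baseline_hz, n), ep[1], ep[2])
  aud_gain <- ifelse(is.na(info$auditory_component), 0,
                     vapply(seq_len(n), function(i) {
                       ac <- info$auditory_component[i]
                       if (is.na(ac)) 0 else nrn[[paste0("gain_", ac)]]
                     }, numeric(1)))
  vis_gain <- ifelse(is.na(info$visual_component), 0,
                     vapply(seq_len(n), function(i) {
                       vc <- info$visual_component[i]
                       if (is.na(vc)) 0 else nrn[[paste0("gain_", vc)]]
                     }, numeric(1)))
  scale <- ifelse(multi, c_eff, 1)
  la <- nrn$auditory_latency_ms
  lv <- nrn$visual_latency_ms
  dur <- nrn$response_duration_ms
  aud <- emit(aud_gain * scale, la, min(la + dur, ep[2]))
  vis <- emit(vis_gain * scale, lv, min(lv + dur, ep[2]))
  out <- dplyr::bind_rows(base, aud, vis)
  if (nrow(out) == 0) return(out)
  out$neuron_id <- nrn$neuron_id
  out[c("neuron_id", "trial_id", "spike_time_ms")]
}

#' Generate a synthetic recording session
#'
#' Simulates a full session of the audiovisual discrimination task:
#' trial labels, choices and reaction times from a [behavior_spec()], and
#' piecewise-constant-rate Poisson spike trains per neuron from a
#' [population_spec()] — baseline rate over the whole epoch plus evoked
#' rates from modality latency to latency + duration, with multisensory
#' trials scaling the summed evoked rates by the pairing's interaction
#' factor (shrunk toward 1 on incorrect choices). The per-neuron ground
#' truth is returned for recovery tests.
#'
#' @param pop an `av_population_spec`.
#' @param behavior an `av_behavior_spec`.
#' @param config an `av_config`.
#' @param seed integer seed; defaults to `pop$seed` then `config$seed`.
#'   Identical seeds give byte-identical sessions.
#' @return An [av_session()] with the `truth` tibble attached.
#' @export
#' @examples
#' s <- generate_session(population_spec(n_neurons = 4, trials_per_cue = 6),
#'                       seed = 1)
#' s$trials
generate_session <- function(pop = population_spec(),
                             behavior = behavior_spec(),
                             config = session_config(),
                             seed = NULL) {
  stopifnot(inherits(pop, "av_population_spec"),
            inherits(behavior, "av_behavior_spec"))
  seed <- seed %||% pop$seed %||% config$seed
  with_seed_if(seed, {
    truth <- draw_neuron_truth(pop)
    trials <- draw_trials(pop, behavior)
    spikes <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      simulate_neuron_spikes(truth[i, ], trials, config)
    })
    spikes <- dplyr::arrange(spikes, .data$neuron_id, .data$trial_id,
                             .data$spike_time_ms)
    av_session(spikes, trials, truth = truth, config = config)
  })
}

#' Preset population/behaviour bundles for named training conditions
#'
#' Returns parameter bundles whose qualitative population statistics mirror
#' the named training condition:
#' \describe{
#'   \item{trained_right_AC}{right-hemisphere recordings after multisensory
#'     training: most neurons prefer the contralateral-choice cues `A10k`
#'     and `Vvt`, visual preference is congruent with auditory preference,
#'     and the `A10kVvt` pairing carries multisensory enhancement
#'     (mean interaction factor 1.5) while `A3kVhz` is additive.}
#'   \item{trained_left_AC}{mirror image under the cue relabelling
#'     `A3k <-> A10k`, `Vhz <-> Vvt`.}
#'   \item{free_choice}{no discrimination requirement: symmetric preferences,
#'     fewer visually responsive neurons, all interaction factors exactly 1,
#'     chance-level choice behaviour.}
#'   \item{unisensory_trained}{sequential auditory-then-visual training:
#'     auditory preference for the contralateral tone persists, visual
#'     preference and multisensory enhancement are absent.}
#'   \item{unmatched_cues}{as trained_right_AC plus the two unmatched
#'     pairings (additive interaction) in the cue pool.}
#' }
#'
#' @param name one of the five preset names.
#' @param n_neurons,trials_per_cue,seed forwarded to [population_spec()].
#' @return `list(pop = av_population_spec, behavior = av_behavior_spec)`.
#' @export
preset_scenario <- function(name = c("trained_right_AC", "trained_left_AC",
                                     "free_choice", "unisensory_trained",
                                     "unmatched_cues"),
                            n_neurons = 200, trials_per_cue = 40,
                            seed = NULL) {
  name <- match.arg(name)
  base <- list(n_neurons = n_neurons, trials_per_cue = trials_per_cue,
               seed = seed)
  flat_interaction <- list(A3kVhz = c(mean = 1, sd = 0),
                           A10kVvt = c(mean = 1, sd = 0),
                           A10kVhz = c(mean = 1, sd = 0),
                           A3kVvt = c(mean = 1, sd = 0))
  spec <- switch(
    name,
    trained_right_AC = c(base, list()),
    trained_left_AC = c(base, list(
      pref_aud_cue = "A3k", pref_vis_cue = "Vhz",
      interaction = list(A3kVhz = c(mean = 1.5, sd = 0.25),
                         A10kVvt = c(mean = 1, sd = 0.1),
                         A10kVhz = c(mean = 1, sd = 0.1),
                         A3kVvt = c(mean = 1, sd = 0.1)))),
    free_choice = c(base, list(
      weights = c(auditory = 0.45, visual = 0.04, audiovisual = 0.14,
                  audiovisual_only = 0, unresponsive = 0.37),
      pref_bias = 0.5, congruence = 0.5,
      gain_means = c(aud_pref = 6, aud_nonpref = 6,
                     vis_pref = 3, vis_nonpref = 3),
      vis_nonpref_zero_prob = 0,
      interaction = flat_interaction)),
    unisensory_trained = c(base, list(
      weights = c(auditory = 0.51, visual = 0.07, audiovisual = 0.14,
                  audiovisual_only = 0, unresponsive = 0.28),
      congruence = 0.5,
      gain_means = c(aud_pref = 8, aud_nonpref = 2.5,
                     vis_pref = 3.5, vis_nonpref = 3.5),
      vis_nonpref_zero_prob = 0.3,
      interaction = flat_interaction)),
    unmatched_cues = c(base, list(include_unmatched = TRUE))
  )
  behavior <- switch(
    name,
    free_choice = behavior_spec(p_correct = c(auditory = 0.5, visual = 0.5,
                                              multisensory = 0.5)),
    behavior_spec()
  )
  list(pop = do.call(population_spec, spec), behavior = behavior)
}
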