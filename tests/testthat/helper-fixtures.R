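# shared fixtures: small deterministic sessions built in code

# trial table with n trials per cue, all with the given correctness
make_trials <- function(cues, n_per_cue, correct = "yes", rt = 300) {
  info <- av_cue_table()
  side <- info$reward_side[match(cues, info$cue)]
  tibble::tibble(
    trial_id = seq_len(length(cues) * n_per_cue),
    cue = rep(cues, each = n_per_cue),
    choice = rep(ifelse(side == "either", "left", side), each = n_per_cue),
    correct = rep(ifelse(side == "either", "either", correct),
                  each = n_per_cue),
    reaction_time_ms = rt)
}

# spike table realising exact per-trial spike counts inside `window`
# counts: named list cue -> integer vector (one count per trial of that cue)
spikes_from_counts <- function(trials, counts, window = c(0, 150),
                               neuron = "n1") {
  rows <- lapply(names(counts), function(cc) {
    ids <- trials$trial_id[trials$cue == cc]
    k <- counts[[cc]]
    stopifnot(length(ids) == length(k))
    tibble::tibble(
      neuron_id = neuron,
      trial_id = rep(ids, k),
      spike_time_ms = unlist(lapply(k, function(n) {
        if (n == 0) numeric(0) else
          window[1] + diff(window) * (seq_len(n) - 0.5) / n
      })))
  })
  dplyr::bind_rows(rows)
}

# one-neuron-per-row Poisson-count session: many independent "neurons"
# sharing one trial set; counts land in `window`, nothing elsewhere
poisson_count_session <- function(n_neurons, rates_by_cue, n_per_cue,
                                  window = c(0, 150), seed = 1) {
  withr::with_seed(seed, {
    trials <- make_trials(names(rates_by_cue), n_per_cue)
    spikes <- dplyr::bind_rows(lapply(seq_len(n_neurons), function(i) {
      per_cue <- lapply(names(rates_by_cue), function(cc) {
        rpois(n_per_cue, rates_by_cue[[cc]] * diff(window) / 1000)
      })
      names(per_cue) <- names(rates_by_cue)
      sp <- spikes_from_counts(trials, per_cue, window,
                               neuron = sprintf("n%04d", i))
      # jitter inside the window so spike times differ across neurons
      sp$spike_time_ms <- runif(nrow(sp), window[1], window[2] - 1e-6)
      sp
    }))
    list(spikes = spikes, trials = trials)
  })
}

# small config for fast tests
fast_config <- function(...) {
  session_config(n_perm = 200, n_boot = 300, min_trials = 3, ...)
}
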