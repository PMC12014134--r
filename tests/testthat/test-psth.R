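test_that("window counting follows the half-open convention", {
  trials <- make_trials("A3k", 2)
  spikes <- tibble::tibble(neuron_id = "n1", trial_id = c(1L, 2L),
                           spike_time_ms = c(5, 150))
  cc <- count_in_window(spikes, trials, c(0, 150))
  expect_equal(cc$n_spikes, c(1L, 0L))  # spike exactly at 150 excluded
  expect_equal(cc$rate_hz[1], 1000 / 150)
  expect_error(count_in_window(spikes, integer(0), c(0, 150)),
               class = "avspike_validation_error")
})

test_that("window counts recover a homogeneous Poisson rate", {
  cfg <- session_config()
  pop <- population_spec(
    n_neurons = 1, trials_per_cue = 170,
    weights = c(auditory = 0, visual = 0, audiovisual = 0,
                audiovisual_only = 0, unresponsive = 1),
    baseline_mean_hz = 20, baseline_shape = 1e9)
  s <- generate_session(pop, config = cfg, seed = 2)
  cc <- count_in_window(s$spikes, s$trials, c(0, 150))
  n <- nrow(cc)
  expect_gt(n, 1000)
  expect_lt(abs(mean(cc$n_spikes) - 3), 3 * sqrt(3 / n))
})

test_that("binned counts partition the epoch", {
  s <- generate_session(population_spec(n_neurons = 2, trials_per_cue = 8),
                        seed = 5)
  cfg <- s$config
  p <- make_psth(s$spikes, s$trials, "n001", cfg, cues = "A10k",
                 correct_only = FALSE)
  n_tr <- p$n_trials$n[1]
  total_from_bins <- sum(p$bins$rate_hz) * cfg$bin_ms * n_tr / 1000
  tr <- s$trials$trial_id[s$trials$cue == "A10k"]
  total_spikes <- sum(s$spikes$trial_id %in% tr & s$spikes$neuron_id == "n001")
  expect_equal(total_from_bins, total_spikes)
})

test_that("the PSTH matches single-spike arithmetic and conserves mass", {
  trials <- make_trials("A3k", 1)
  spikes <- tibble::tibble(neuron_id = "n1", trial_id = 1L,
                           spike_time_ms = 5)
  p <- make_psth(spikes, trials, "n1")
  b <- p$bins
  expect_equal(b$rate_hz[b$bin_start == 0], 100)
  expect_equal(sum(b$rate_hz), 100)
  # Gaussian smoothing preserves the time-integral away from the edges
  expect_lt(abs(sum(b$smoothed_hz) - sum(b$rate_hz)) / sum(b$rate_hz), 0.01)
  # flat baseline -> zero SD -> degenerate z, flagged not infinite
  expect_true(p$baseline$degenerate[1])
  expect_true(all(is.na(b$z)))
})

test_that("baseline z-scores are centred for a constant-rate neuron", {
  cfg <- session_config()
  pop <- population_spec(
    n_neurons = 25, trials_per_cue = 25,
    weights = c(auditory = 0, visual = 0, audiovisual = 0,
                audiovisual_only = 0, unresponsive = 1),
    baseline_mean_hz = 12, baseline_shape = 1e9)
  s <- generate_session(pop, config = cfg, seed = 11)
  mean_z <- vapply(unique(s$spikes$neuron_id), function(nn) {
    p <- make_psth(s$spikes, s$trials, nn, cfg, cues = "A10k")
    mean(p$bins$z[p$bins$bin_start >= 0 & p$bins$bin_start < 1000])
  }, numeric(1))
  se <- sd(mean_z) / sqrt(length(mean_z))
  expect_lt(abs(mean(mean_z)), 3 * se + 0.05)
})

test_that("responsiveness requires both the rate gate and the test", {
  cfg <- session_config(min_trials = 5)
  trials <- make_trials("A3k", 40)
  # sub-threshold: 1 spike in half the trials -> ~1.7 spikes/s evoked,
  # wildly significant, but the 2 spikes/s gate fails
  weak <- spikes_from_counts(trials, list(A3k = rep(c(1L, 0L), 20)),
                             window = c(0, 300))
  r_weak <- classify_responsiveness(weak, trials, cfg)
  expect_lt(r_weak$p_value, 0.05)
  expect_lt(r_weak$evoked_hz, 2)
  expect_false(r_weak$responsive)
  # strong: 3 spikes on every trial -> 10 spikes/s, responsive
  strong <- spikes_from_counts(trials, list(A3k = rep(3L, 40)),
                               window = c(0, 300))
  r_strong <- classify_responsiveness(strong, trials, cfg)
  expect_true(r_strong$responsive)
  # silence: degenerate signed-rank, called non-responsive
  silent <- tibble::tibble(neuron_id = "n1", trial_id = 1L,
                           spike_time_ms = -500)
  r_silent <- classify_responsiveness(silent, trials, cfg)
  expect_true(r_silent$degenerate)
  expect_false(r_silent$responsive)
})

test_that("response categories follow the modality taxonomy", {
  resp <- tidyr::expand_grid(
    neuron_id = c("a", "v", "av", "avonly", "none"),
    cue = c("A3k", "Vhz", "A3kVhz"))
  resp$responsive <- with(resp, (neuron_id == "a" & cue == "A3k") |
    (neuron_id == "v" & cue == "Vhz") |
    (neuron_id == "av" & cue %in% c("A3k", "Vhz")) |
    (neuron_id == "avonly" & cue == "A3kVhz"))
  cats <- categorize_neurons(resp)
  expect_equal(cats$category[match(c("a", "v", "av", "avonly", "none"),
                                   cats$neuron_id)],
               c("A", "V", "AV", "AV-only", "unresponsive"))
})

test_that("the whole-epoch activity screen keeps only active units", {
  trials <- make_trials("A3k", 10)
  # 2.2 s epoch: 2 Hz needs >= 4.4 spikes/trial on average
  act_spikes <- dplyr::bind_rows(
    spikes_from_counts(trials, list(A3k = rep(6L, 10)), c(0, 1000), "hot"),
    spikes_from_counts(trials, list(A3k = rep(1L, 10)), c(0, 1000), "cold"))
  act <- active_neurons(act_spikes, trials)
  expect_true(act$active[act$neuron_id == "hot"])
  expect_false(act$active[act$neuron_id == "cold"])
})
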