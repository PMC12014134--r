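pseudo_cfg <- function(...) {
  session_config(decoding = modifyList(
    list(window_ms = 100, step_ms = 10, trials_per_cue = 30, min_trials = 30,
         folds = 5, resamples = 3, shuffles = 30, range_ms = c(0, 100)),
    list(...)))
}

test_that("pseudo-population shapes follow the construction law", {
  trials <- make_trials(c("A3k", "A10k"), 30)
  spikes <- spikes_from_counts(trials, list(A3k = rep(1L, 30),
                                            A10k = rep(2L, 30)))
  s <- av_session(spikes, trials)
  pop <- build_pseudopopulation(s, "A3k", "A10k", pseudo_cfg(), seed = 1)
  expect_equal(dim(pop$x), c(60, 1, 1))  # M = 60, N = 1, one window
  expect_equal(as.character(unique(pop$y)), c("A3k", "A10k"))
  expect_equal(dim(pop$provenance), c(60, 1))
  # every drawn trial really belongs to its class
  cls <- s$trials$cue[match(pop$provenance[, 1], s$trials$trial_id)]
  expect_equal(cls, as.character(pop$y))

  # a neuron with 29 trials in one class is excluded (session-level here)
  short <- trials[-1, ]
  s29 <- av_session(spikes[spikes$trial_id != 1, ], short)
  expect_error(build_pseudopopulation(s29, "A3k", "A10k", pseudo_cfg()),
               class = "avspike_validation_error")

  # neurons from multiple sessions concatenate
  s2 <- av_session(dplyr::mutate(spikes, neuron_id = "m1"), trials)
  pop2 <- build_pseudopopulation(list(s, s2), "A3k", "A10k", pseudo_cfg(),
                                 seed = 2)
  expect_equal(dim(pop2$x)[2], 2)
  expect_equal(pop2$neurons$session, c(1, 2))
})

test_that("sliding-window counts match direct window counting", {
  cfg <- pseudo_cfg(range_ms = c(-100, 200), trials_per_cue = 30)
  s <- generate_session(population_spec(
    n_neurons = 2, trials_per_cue = 35, baseline_mean_hz = 15,
    weights = c(auditory = 0, visual = 0, audiovisual = 0,
                audiovisual_only = 0, unresponsive = 1)),
    behavior_spec(p_correct = c(auditory = 1, visual = 1,
                                multisensory = 1)), seed = 3)
  pop <- build_pseudopopulation(s, "A3k", "A10k", cfg, seed = 4)
  # check one window against count_in_window for the provenance trials
  w <- 7
  ws <- pop$windows$start[w]
  for (j in 1:2) {
    nn <- pop$neurons$neuron_id[j]
    cc <- count_in_window(s$spikes, pop$provenance[, j], c(ws, ws + 100),
                          neurons = nn)
    expect_equal(pop$x[, j, w],
                 cc$n_spikes[match(pop$provenance[, j], cc$trial_id)])
  }
})

test_that("strong rate separation decodes and chance stays at one half", {
  cfg <- pseudo_cfg(range_ms = c(-150, 250), resamples = 4, shuffles = 60,
                    min_trials = 25, trials_per_cue = 25)
  pop <- population_spec(
    n_neurons = 10, trials_per_cue = 40,
    weights = c(auditory = 1, visual = 0, audiovisual = 0,
                audiovisual_only = 0, unresponsive = 0),
    baseline_mean_hz = 3,
    gain_means = c(aud_pref = 25, aud_nonpref = 0, vis_pref = 0,
                   vis_nonpref = 0),
    gain_shape = 1e9, pref_bias = 1)
  s <- generate_session(pop, behavior_spec(), cfg, seed = 5)
  d <- decode_timecourse(s, "A10k", "A3k", cfg, seed = 6)
  w <- d$windows
  expect_gt(max(w$accuracy[w$center > 50]), 0.9)
  pre <- w$accuracy[w$center <= -50]
  expect_true(all(pre >= d$null$lower - 0.1 & pre <= d$null$upper + 0.1))
  expect_lt(abs(d$null$mean - 0.5), 0.08)
  expect_true(all(w$accuracy >= 0 & w$accuracy <= 1))
  # crossing convention: earliest window centre at or above the level
  cross <- first_crossing_time(d, 0.9)
  expect_equal(cross, min(w$center[w$accuracy >= 0.9]))
})

test_that("crossing times follow the stated conventions", {
  fake <- structure(list(
    windows = tibble::tibble(center = c(-50, 0, 50, 100),
                             accuracy = c(0.5, 0.5, 0.5, 0.5), sd = 0),
    null = list(), params = list()), class = "av_decoding")
  expect_true(is.na(first_crossing_time(fake)))
  fake$windows$accuracy <- c(0.5, 0.7, 0.93, 0.97)
  expect_equal(first_crossing_time(fake, 0.9), 50)
})

test_that("accuracy is invariant under common count rescaling", {
  trials <- make_trials(c("A3k", "A10k"), 30)
  withr::with_seed(7, {
    spikes <- dplyr::bind_rows(lapply(1:6, function(i) {
      cnt <- list(A3k = rpois(30, 2), A10k = rpois(30, 5))
      spikes_from_counts(trials, cnt, c(0, 100), sprintf("n%d", i))
    }))
  })
  s <- av_session(spikes, trials)
  pop <- build_pseudopopulation(s, "A3k", "A10k", pseudo_cfg(), seed = 8)
  xm <- avspike:::slice_window(pop, 1)
  withr::with_seed(9, {
    folds <- avspike:::stratified_folds(pop$y, 5)
    a1 <- avspike:::svm_cv_accuracy(xm, pop$y, folds, cost = 1)
    a3 <- avspike:::svm_cv_accuracy(3 * xm, pop$y, folds, cost = 1)
  })
  expect_lt(abs(a1 - a3), 0.12)
})

test_that("the pairwise decoding matrix is symmetric with 0.5 diagonal", {
  cfg <- pseudo_cfg(resamples = 2, min_trials = 20, trials_per_cue = 20)
  pop <- population_spec(
    n_neurons = 6, trials_per_cue = 30,
    weights = c(auditory = 1, visual = 0, audiovisual = 0,
                audiovisual_only = 0, unresponsive = 0),
    baseline_mean_hz = 4,
    gain_means = c(aud_pref = 20, aud_nonpref = 0, vis_pref = 0,
                   vis_nonpref = 0), pref_bias = 1)
  s <- generate_session(pop, behavior_spec(), cfg, seed = 10)
  m <- decoding_matrix(s, cues = c("A3k", "A10k", "Vhz"), window = c(0, 150),
                       config = cfg, seed = 11)
  expect_equal(m$accuracy, t(m$accuracy))
  expect_equal(unname(diag(m$accuracy)), rep(0.5, 3))
  # separable pair beats the identical pair
  expect_gt(m$accuracy["A3k", "A10k"], m$accuracy["A3k", "Vhz"])
  expect_error(decoding_matrix(s, cues = av_cues(), config = cfg),
               class = "avspike_validation_error", regexp = "A10kVhz")
  expect_equal(dim(tidy(m)), c(9L, 3L))
})
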