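test_that("identical seeds reproduce identical sessions", {
  pop <- population_spec(n_neurons = 4, trials_per_cue = 8)
  a <- generate_session(pop, seed = 7)
  b <- generate_session(pop, seed = 7)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth, b$truth)
  c <- generate_session(pop, seed = 8)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("baseline spiking matches the Poisson mean and dispersion", {
  # single flat neuron, ~200 one-second trials at 5 spikes/s
  cfg <- session_config(epoch = c(-400, 1000))
  pop <- population_spec(
    n_neurons = 1, trials_per_cue = 34,
    weights = c(auditory = 0, visual = 0, audiovisual = 0,
                audiovisual_only = 0, unresponsive = 1),
    baseline_mean_hz = 5, baseline_shape = 1e9)
  s <- generate_session(pop, config = cfg, seed = 3)
  cc <- count_in_window(s$spikes, s$trials, c(0, 1000))
  n <- nrow(cc)
  expect_gt(n, 150)
  se <- sqrt(5 / n)
  expect_lt(abs(mean(cc$n_spikes) - 5), 3 * se)
  # Poisson dispersion: variance/mean near 1 on a constant-rate segment
  expect_lt(abs(var(cc$n_spikes) / mean(cc$n_spikes) - 1),
            3 * sqrt(2 / n) + 0.05)
})

test_that("interaction-free pairings add no multisensory advantage", {
  # audiovisual neurons whose Vhz gain is zero and whose interaction is 1:
  # the A3kVhz response equals the auditory response, so the population MSI
  # for that pairing sits at zero
  pop <- population_spec(
    n_neurons = 120, trials_per_cue = 14,
    weights = c(auditory = 0, visual = 0, audiovisual = 1,
                audiovisual_only = 0, unresponsive = 0),
    gain_means = c(aud_pref = 8, aud_nonpref = 8, vis_pref = 6,
                   vis_nonpref = 0),
    vis_nonpref_zero_prob = 1, pref_bias = 1, congruence = 1,
    interaction = list(A3kVhz = c(mean = 1, sd = 0),
                       A10kVvt = c(mean = 1, sd = 0),
                       A10kVhz = c(mean = 1, sd = 0),
                       A3kVvt = c(mean = 1, sd = 0)))
  s <- generate_session(pop, behavior_spec(p_correct = c(
    auditory = 1, visual = 1, multisensory = 1)), seed = 4)
  m <- msi(s$spikes, s$trials, "A3kVhz", config = fast_config(), n_perm = 0)
  se <- sd(m$msi) / sqrt(nrow(m))
  expect_lt(abs(mean(m$msi)), 3 * se + 0.01)
})

test_that("presets encode the named training conditions", {
  right <- preset_scenario("trained_right_AC", n_neurons = 150,
                           trials_per_cue = 10)
  left <- preset_scenario("trained_left_AC", n_neurons = 150,
                          trials_per_cue = 10)
  free <- preset_scenario("free_choice")
  uni <- preset_scenario("unisensory_trained")
  unm <- preset_scenario("unmatched_cues")

  # left mirrors right under the cue relabelling A3k<->A10k, Vhz<->Vvt
  expect_identical(left$pop$pref_aud_cue, "A3k")
  expect_identical(left$pop$pref_vis_cue, "Vhz")
  expect_equal(left$pop$interaction$A3kVhz,
               right$pop$interaction$A10kVvt)
  expect_equal(left$pop$interaction$A10kVvt,
               right$pop$interaction$A3kVhz)

  # free choice: all interaction factors exactly 1, symmetric preferences
  s_free <- generate_session(free$pop, free$behavior, seed = 5)
  expect_true(all(s_free$truth$c_A10kVvt == 1 & s_free$truth$c_A3kVhz == 1))
  expect_equal(free$pop$pref_bias, 0.5)

  # trained right: majority of tuned neurons prefer A10k over A3k
  s_right <- generate_session(right$pop, right$behavior, seed = 6)
  tr <- s_right$truth[s_right$truth$gain_A10k + s_right$truth$gain_A3k > 0, ]
  expect_gt(sum(tr$gain_A10k > tr$gain_A3k), sum(tr$gain_A3k > tr$gain_A10k))

  # unisensory training: no visual-preference asymmetry built in
  expect_equal(uni$pop$gain_means[["vis_pref"]],
               uni$pop$gain_means[["vis_nonpref"]])
  expect_equal(uni$pop$interaction$A10kVvt[["mean"]], 1)

  # unmatched preset generates all 8 cues
  s_unm <- generate_session(unm$pop, unm$behavior,
                            seed = 7)
  expect_setequal(unique(s_unm$trials$cue), av_cues())
  expect_true(all(s_unm$trials$correct[
    s_unm$trials$cue %in% c("A10kVhz", "A3kVvt")] == "either"))
})

test_that("incorrect-choice shrink weakens only multisensory responses", {
  pop <- population_spec(
    n_neurons = 40, trials_per_cue = 30,
    weights = c(auditory = 0, visual = 0, audiovisual = 1,
                audiovisual_only = 0, unresponsive = 0),
    gain_means = c(aud_pref = 10, aud_nonpref = 10, vis_pref = 8,
                   vis_nonpref = 8),
    vis_nonpref_zero_prob = 0, pref_bias = 1, congruence = 1,
    interaction = list(A3kVhz = c(mean = 2, sd = 0),
                       A10kVvt = c(mean = 2, sd = 0),
                       A10kVhz = c(mean = 2, sd = 0),
                       A3kVvt = c(mean = 2, sd = 0)),
    incorrect_shrink = 0)
  beh <- behavior_spec(p_correct = c(auditory = 0.6, visual = 0.6,
                                     multisensory = 0.6))
  s <- generate_session(pop, beh, seed = 9)
  tr_av <- s$trials[s$trials$cue == "A10kVvt", ]
  cc <- count_in_window(s$spikes, tr_av, c(0, 200))
  cc <- dplyr::left_join(cc, tr_av[c("trial_id", "correct")], by = "trial_id")
  m_corr <- mean(cc$n_spikes[cc$correct == "yes"])
  m_inc <- mean(cc$n_spikes[cc$correct == "no"])
  expect_gt(m_corr, m_inc)
  # unisensory responses unaffected by choice
  tr_a <- s$trials[s$trials$cue == "A10k", ]
  ca <- count_in_window(s$spikes, tr_a, c(0, 200))
  ca <- dplyr::left_join(ca, tr_a[c("trial_id", "correct")], by = "trial_id")
  d <- mean(ca$n_spikes[ca$correct == "yes"]) -
    mean(ca$n_spikes[ca$correct == "no"])
  expect_lt(abs(d), 3 * sd(ca$n_spikes) * sqrt(2 / nrow(tr_a) * 3))
})

test_that("degenerate generator requests are rejected", {
  expect_error(population_spec(trials_per_cue = 0),
               class = "avspike_validation_error")
  expect_error(population_spec(weights = c(auditory = 1, visual = 1,
                                           audiovisual = 0,
                                           audiovisual_only = 0,
                                           unresponsive = 0)),
               class = "avspike_validation_error")
  expect_error(preset_scenario("no_such_condition"))
})
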