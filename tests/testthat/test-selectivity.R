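test_that("auROC matches hand-computed values", {
  expect_equal(as.numeric(compute_auroc(c(1, 1, 1), c(1, 1, 1))), 0.5)
  expect_true(attr(compute_auroc(c(1, 1, 1), c(1, 1, 1)), "degenerate"))
  expect_equal(compute_auroc(c(10, 11, 12), c(0, 1, 2)), 1)
  expect_equal(compute_auroc(c(1, 2, 3), c(0, 1, 2)), 7 / 9)
  expect_error(compute_auroc(1, c(1, 2)), class = "avspike_validation_error")
})

test_that("rank auROC equals the cross-pair oracle on random counts", {
  brute <- function(a, b) mean(outer(a, b, ">") + 0.5 * outer(a, b, "=="))
  withr::with_seed(21, {
    for (i in 1:200) {
      a <- rpois(sample(2:40, 1), runif(1, 0, 8))
      b <- rpois(sample(2:40, 1), runif(1, 0, 8))
      if (min(c(a, b)) == max(c(a, b))) next
      expect_equal(as.numeric(compute_auroc(a, b)), brute(a, b))
    }
  })
})

test_that("criterion-sweep auROC is exact for <= 12 grid-spanning values", {
  withr::with_seed(22, {
    for (i in 1:50) {
      a <- sample(0:11, 20, replace = TRUE)
      b <- sample(0:11, 25, replace = TRUE)
      a[1] <- 0; b[1] <- 11  # force the pooled range to span the grid
      expect_equal(compute_auroc(a, b, "discretized12"),
                   compute_auroc(a, b, "exact_rank"))
    }
  })
})

test_that("the selectivity index is antisymmetric and rank-invariant", {
  cfg <- fast_config()
  trials <- make_trials(c("A3k", "A10k"), 3)
  spikes <- spikes_from_counts(trials, list(A10k = c(1L, 2L, 3L),
                                            A3k = c(0L, 1L, 2L)))
  si_ab <- selectivity_index(spikes, trials, "A10k", "A3k", config = cfg,
                             n_perm = 0)
  expect_equal(si_ab$si, 2 * (7 / 9 - 0.5))  # 5/9
  si_ba <- selectivity_index(spikes, trials, "A3k", "A10k", config = cfg,
                             n_perm = 0)
  expect_equal(si_ba$si, -si_ab$si)
  # invariance under a strictly monotone transform of the counts: square
  # the per-trial counts by squaring spike multiplicities
  spikes_sq <- spikes_from_counts(trials, list(A10k = c(1L, 4L, 9L),
                                               A3k = c(0L, 1L, 4L)))
  si_sq <- selectivity_index(spikes_sq, trials, "A10k", "A3k", config = cfg,
                             n_perm = 0)
  expect_equal(si_sq$si, si_ab$si)
})

test_that("identical conditions give zero, non-significant selectivity", {
  trials <- make_trials(c("A3k", "A10k"), 8)
  spikes <- spikes_from_counts(trials, list(A10k = rep(2L, 8),
                                            A3k = rep(2L, 8)))
  si <- selectivity_index(spikes, trials, "A10k", "A3k",
                          config = fast_config(), seed = 1)
  expect_equal(si$si, 0)
  expect_true(si$degenerate)
  expect_false(isTRUE(si$significant))
  # insufficient trials error names the cue
  few <- make_trials(c("A3k", "A10k"), 2)
  expect_error(
    selectivity_index(spikes_from_counts(few, list(A3k = c(1L, 2L),
                                                   A10k = c(1L, 2L))),
                      few, "A10k", "A3k"),
    class = "avspike_insufficient_trials", regexp = "A10k")
})

test_that("MSI compares the pairing against its stronger component", {
  cfg <- fast_config()
  trials <- make_trials(c("A3k", "Vhz", "A3kVhz"), 3)
  # equal multisensory and auditory responses -> MSI 0, auditory tie-break
  m0 <- msi(spikes_from_counts(trials, list(A3kVhz = c(5L, 5L, 5L),
                                            A3k = c(5L, 5L, 5L),
                                            Vhz = c(2L, 2L, 2L))),
            trials, "A3kVhz", config = cfg, n_perm = 0)
  expect_equal(m0$stronger_unisensory, "A3k")
  expect_equal(m0$msi, 0)
  # graded case reproduces the pair-count oracle (5/9)
  m1 <- msi(spikes_from_counts(trials, list(A3kVhz = c(3L, 4L, 5L),
                                            A3k = c(2L, 3L, 4L),
                                            Vhz = c(1L, 1L, 2L))),
            trials, "A3kVhz", config = cfg, n_perm = 0)
  expect_equal(m1$stronger_unisensory, "A3k")
  expect_equal(m1$msi, 5 / 9)
  # multisensory response below both components -> complete separation
  m2 <- msi(spikes_from_counts(trials, list(A3kVhz = c(0L, 0L, 1L),
                                            A3k = c(4L, 5L, 6L),
                                            Vhz = c(2L, 3L, 3L))),
            trials, "A3kVhz", config = cfg, n_perm = 0)
  expect_equal(m2$msi, -1)
  expect_error(msi(m1, trials, "A3k", config = cfg),
               class = "avspike_validation_error")
})

test_that("choice-split MSI enforces the per-choice trial minimum", {
  cfg <- session_config(min_trials_choice = 9)
  info_cues <- c("A3k", "Vhz", "A3kVhz")
  trials <- make_trials(info_cues, 20)
  # flip 8 trials of each cue to incorrect: below the 9-trial minimum
  flip <- unlist(lapply(info_cues, function(cc) {
    head(trials$trial_id[trials$cue == cc], 8)
  }))
  trials$correct[trials$trial_id %in% flip] <- "no"
  spikes <- spikes_from_counts(
    dplyr::mutate(trials, correct = "yes"),
    list(A3kVhz = rep(3L, 20), A3k = rep(2L, 20), Vhz = rep(1L, 20)))
  out <- msi_by_choice(spikes, trials, "A3kVhz", config = cfg)
  expect_true(all(out$excluded))
  expect_match(out$reason[1], "below 9 trials")
  # with 9 incorrect trials per cue the computation proceeds
  extra <- unlist(lapply(info_cues, function(cc) {
    trials$trial_id[trials$cue == cc & trials$correct == "yes"][1]
  }))
  trials$correct[trials$trial_id %in% extra] <- "no"
  ok <- msi_by_choice(spikes, trials, "A3kVhz", config = cfg)
  expect_false(any(ok$excluded))
  expect_setequal(ok$choice, c("correct", "incorrect"))
  expect_true(all(is.finite(ok$msi)))
})

test_that("the delta-MSI / delta-selectivity correlation is well-formed", {
  sc <- preset_scenario("trained_right_AC", n_neurons = 40,
                        trials_per_cue = 20, seed = 31)
  s <- generate_session(sc$pop, sc$behavior, seed = 31)
  r <- delta_msi_selectivity(s$spikes, s$trials, config = fast_config())
  expect_s3_class(r, "av_correlation")
  expect_equal(r$n, nrow(r$data))
  expect_true(abs(r$estimate) <= 1)
  expect_named(tidy(r), c("neuron_id", "delta_msi", "delta_si"))
  expect_true(is.finite(glance(r)$p_value))
})

test_that("permutation p-values are calibrated two-tailed tail positions", {
  withr::with_seed(33, {
    a <- rpois(30, 2)
    b <- rpois(30, 8)
    r <- avspike:::auroc_perm_test(a, b, 199)
    expect_equal(r$p_value, 2 / 200)  # most extreme possible, add-one rule
    expect_true(r$significant)
  })
})
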