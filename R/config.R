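#' Analysis configuration for a recording session
#'
#' Bundles the epoch bounds, analysis windows, binning and resampling
#' parameters used throughout the pipeline. Defaults follow the conventions
#' of the task analyses: spikes aligned to cue onset in ms, half-open
#' windows, a 400 ms pre-cue baseline, an early 0-150 ms analysis window,
#' 10 ms bins smoothed with a 50 ms Gaussian kernel, 2000 permutations and
#' 5000 bootstrap iterations.
#'
#' @param epoch recorded epoch bounds `c(start, end)` in ms relative to cue
#'   onset (spikes outside are invalid).
#' @param baseline_window pre-cue window for baseline statistics, ms.
#' @param analysis_window early response window used for selectivity, MSI and
#'   additivity, ms.
#' @param late_window late response window, ms.
#' @param responsiveness_window window for the responsiveness screen, ms.
#' @param bin_ms PSTH bin width, ms.
#' @param smooth_sd_ms Gaussian smoothing kernel standard deviation, ms.
#' @param n_perm permutation count for selectivity/MSI significance.
#' @param n_boot bootstrap iteration count for the additive-model test.
#' @param alpha significance level for all per-neuron tests.
#' @param response_threshold_hz minimum baseline-subtracted evoked rate
#'   (spikes/s) for a cue response to count as responsive.
#' @param min_rate_hz whole-epoch mean-rate inclusion threshold (spikes/s).
#' @param min_trials minimum usable trials per condition for selectivity,
#'   MSI and additivity computations.
#' @param min_trials_choice minimum trials per choice (correct/incorrect) per
#'   cue for the choice-split MSI analysis.
#' @param decoding named list of decoding parameters; defaults:
#'   `window_ms = 100`, `step_ms = 10`, `trials_per_cue = 30`,
#'   `min_trials = 30`, `folds = 10`, `resamples = 100`, `shuffles = 1000`,
#'   `cost = 1`, `range_ms = NULL` (full epoch).
#' @param seed optional integer seed recorded with the configuration.
#' @return An object of class `av_config` (a validated named list).
#' @export
#' @examples
#' cfg <- session_config(n_perm = 500)
#' cfg$analysis_window
session_config <- function(epoch = c(-700, 1500),
                           baseline_window = c(-400, 0),
                           analysis_window = c(0, 150),
                           late_window = c(150, 300),
                           responsiveness_window = c(0, 300),
                           bin_ms = 10,
                           smooth_sd_ms = 50,
                           n_perm = 2000,
                           n_boot = 5000,
                           alpha = 0.05,
                           response_threshold_hz = 2,
                           min_rate_hz = 2,
                           min_trials = 5,
                           min_trials_choice = 9,
                           decoding = list(),
                           seed = NULL) {
  check_window(epoch, name = "epoch")
  for (nm in c("baseline_window", "analysis_window", "late_window",
               "responsiveness_window")) {
    check_window(get(nm), epoch, name = nm)
  }
  check_number(bin_ms, "bin_ms", min = 1e-9)
  check_number(smooth_sd_ms, "smooth_sd_ms", min = 0)
  check_number(n_perm, "n_perm", min = 0)
  check_number(n_boot, "n_boot", min = 1)
  check_number(alpha, "alpha", min = 1e-12)
  check_number(response_threshold_hz, "response_threshold_hz", min = 0)
  check_number(min_rate_hz, "min_rate_hz", min = 0)
  check_number(min_trials, "min_trials", min = 1)
  check_number(min_trials_choice, "min_trials_choice", min = 1)
  dec_default <- list(window_ms = 100, step_ms = 10, trials_per_cue = 30,
                      min_trials = 30, folds = 10, resamples = 100,
                      shuffles = 1000, cost = 1, range_ms = NULL)
  bad <- setdiff(names(decoding), names(dec_default))
  if (length(bad)) {
    abort(paste0("unknown decoding parameter(s): ", paste(bad, collapse = ", ")),
          class = "avspike_validation_error")
  }
  dec <- modifyList(dec_default, decoding, keep.null = TRUE)
  for (nm in setdiff(names(dec_default), "range_ms")) {
    check_number(dec[[nm]], paste0("decoding$", nm), min = 1e-9)
  }
  if (!is.null(dec$range_ms)) check_window(dec$range_ms, epoch, "decoding$range_ms")
  structure(
    list(epoch = as.numeric(epoch),
         baseline_window = as.numeric(baseline_window),
         analysis_window = as.numeric(analysis_window),
         late_window = as.numeric(late_window),
         responsiveness_window = as.numeric(responsiveness_window),
         bin_ms = bin_ms, smooth_sd_ms = smooth_sd_ms,
         n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
         alpha = alpha, response_threshold_hz = response_threshold_hz,
         min_rate_hz = min_rate_hz, min_trials = as.integer(min_trials),
         min_trials_choice = as.integer(min_trials_choice),
         decoding = dec,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "av_config"
  )
}

#' @export
print.av_config <- function(x, ...) {
  cat("<av_config>\n")
  cat(sprintf("  epoch [%g, %g) ms; baseline [%g, %g); analysis [%g, %g)\n",
              x$epoch[1], x$epoch[2], x$baseline_window[1], x$baseline_window[2],
              x$analysis_window[1], x$analysis_window[2]))
  cat(sprintf("  bins %g ms, smoothing sd %g ms; %d permutations, %d bootstraps\n",
              x$bin_ms, x$smooth_sd_ms, x$n_perm, x$n_boot))
  cat(sprintf("  decoding: %g ms windows / %g ms step, %d trials/cue, %d folds\n",
              x$decoding$window_ms, x$decoding$step_ms,
              as.integer(x$decoding$trials_per_cue), as.integer(x$decoding$folds)))
  invisible(x)
}

#' Read or write a session configuration file
#'
#' Configurations are stored as YAML (`.yml`/`.yaml`) or JSON (`.json`);
#' the keys are the arguments of [session_config()], which validates on read.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_config()` returns an `av_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "avspike_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(session_config, raw)
}

#' @rdname read_config
#' @param config an `av_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "av_config"))
  plain <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}
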