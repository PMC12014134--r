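#' Bundle spike and trial tables into a session object
#'
#' A session is a pair of long-format tables: one row per spike
#' (`neuron_id`, `trial_id`, `spike_time_ms` relative to cue onset) and one
#' row per trial (`trial_id`, `cue`, `choice`, `correct`, `reaction_time_ms`).
#' `correct` is `"yes"`/`"no"`, or `"either"` for unmatched multisensory cues
#' where both ports are rewarded. Construction validates both tables and
#' their referential integrity.
#'
#' @param spikes data frame with columns `neuron_id`, `trial_id`,
#'   `spike_time_ms`.
#' @param trials data frame with columns `trial_id`, `cue`, `choice`,
#'   `correct`, `reaction_time_ms`.
#' @param truth optional per-neuron ground-truth tibble (from the generator).
#' @param config `av_config`; supplies the epoch bounds spikes must lie in.
#' @return An `av_session`: list with elements `spikes`, `trials`, `truth`,
#'   `config`.
#' @export
av_session <- function(spikes, trials, truth = NULL, config = session_config()) {
  trials <- validate_trial_table(trials)
  spikes <- validate_spike_table(spikes, trials, config)
  structure(list(spikes = spikes, trials = trials, truth = truth,
                 config = config),
            class = "av_session")
}

#' @export
print.av_session <- function(x, ...) {
  cat("<av_session>\n")
  cat(sprintf("  %d spikes, %d neurons, %d trials (%s)\n",
              nrow(x$spikes), dplyr::n_distinct(x$spikes$neuron_id),
              nrow(x$trials),
              paste(sort(unique(x$trials$cue)), collapse = ", ")))
  if (!is.null(x$truth)) cat("  generator ground truth attached\n")
  invisible(x)
}

#' Validate a trial-metadata table
#'
#' Checks column presence and types, uniqueness of `trial_id`, the 8-cue
#' enumeration, the choice enumeration (`left`/`right`/`none`), the
#' `correct` coding (`yes`/`no`/`either`) and non-negative reaction times
#' (missing allowed).
#'
#' @param trials data frame to validate.
#' @return The validated table as a tibble (column order normalised).
#' @export
validate_trial_table <- function(trials) {
  required <- c("trial_id", "cue", "choice", "correct", "reaction_time_ms")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "avspike_schema_error")
  }
  trials <- tibble::as_tibble(trials)[required]
  if (anyDuplicated(trials$trial_id)) {
    dup <- unique(trials$trial_id[duplicated(trials$trial_id)])
    abort(paste0("duplicated trial_id(s): ",
                 paste(head(dup, 10), collapse = ", ")),
          class = "avspike_validation_error")
  }
  bad_cue <- setdiff(unique(trials$cue), av_cues())
  if (length(bad_cue)) {
    abort(paste0("cue values outside the 8-cue set: ",
                 paste(bad_cue, collapse = ", ")),
          class = "avspike_validation_error")
  }
  bad_choice <- setdiff(unique(trials$choice), c("left", "right", "none"))
  if (length(bad_choice)) {
    abort(paste0("choice values must be left/right/none; found: ",
                 paste(bad_choice, collapse = ", ")),
          class = "avspike_validation_error")
  }
  bad_corr <- setdiff(unique(trials$correct), c("yes", "no", "either"))
  if (length(bad_corr)) {
    abort(paste0("correct values must be yes/no/either; found: ",
                 paste(bad_corr, collapse = ", ")),
          class = "avspike_validation_error")
  }
  rt <- trials$reaction_time_ms
  if (!is.numeric(rt)) {
    abort("reaction_time_ms must be numeric (empty for missing)",
          class = "avspike_schema_error")
  }
  if (any(rt < 0, na.rm = TRUE)) {
    abort("reaction_time_ms must be >= 0 when present",
          class = "avspike_validation_error")
  }
  trials$trial_id <- as.integer(trials$trial_id)
  trials
}

#' Validate a spike table against its trial table
#'
#' Checks column presence, numeric spike times, that every `trial_id` exists
#' in the companion trial table (dangling references are an error, never
#' silently dropped) and that spike times lie within the session epoch.
#'
#' @param spikes data frame to validate.
#' @param trials companion (already validated) trial table.
#' @param config `av_config` supplying the epoch.
#' @return The validated spike table as a tibble.
#' @export
validate_spike_table <- function(spikes, trials, config = session_config()) {
  required <- c("neuron_id", "trial_id", "spike_time_ms")
  missing <- setdiff(required, names(spikes))
  if (length(missing)) {
    abort(paste0("spike table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "avspike_schema_error")
  }
  spikes <- tibble::as_tibble(spikes)[required]
  if (!is.numeric(spikes$spike_time_ms)) {
    abort("spike_time_ms must be numeric", class = "avspike_schema_error")
  }
  dangling <- setdiff(unique(spikes$trial_id), trials$trial_id)
  if (length(dangling)) {
    abort(paste0("spike rows reference trial_id(s) absent from the trial ",
                 "table: ", paste(head(sort(dangling), 10), collapse = ", ")),
          class = "avspike_integrity_error")
  }
  ep <- config$epoch
  out_of_epoch <- spikes$spike_time_ms < ep[1] | spikes$spike_time_ms >= ep[2]
  if (any(out_of_epoch)) {
    abort(sprintf("%d spike time(s) outside the epoch [%g, %g)",
                  sum(out_of_epoch), ep[1], ep[2]),
          class = "avspike_validation_error")
  }
  spikes$neuron_id <- as.character(spikes$neuron_id)
  spikes$trial_id <- as.integer(spikes$trial_id)
  spikes
}

# read a csv as character columns, then convert one column to numeric,
# reporting offending file lines (header is line 1)
convert_numeric_column <- function(x, col, path) {
  raw <- x[[col]]
  blank <- is.na(raw) | trimws(raw) == ""
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(!blank & is.na(num))
  if (length(bad)) {
    abort(sprintf("non-numeric %s in %s at line(s): %s", col, basename(path),
                  paste(head(bad + 1L, 10), collapse = ", ")),
          class = "avspike_parse_error")
  }
  num
}

#' Read a session from delimited text files
#'
#' Reads `spikes.csv` (columns `neuron_id,trial_id,spike_time_ms`) and
#' `trials.csv` (columns `trial_id,cue,choice,correct,reaction_time_ms`),
#' validates both (schema, enumerations, referential integrity, epoch
#' bounds) and returns an [av_session()]. Missing reaction times are empty
#' fields, distinct from zero.
#'
#' @param spike_path,trial_path file paths; alternatively give `dir` holding
#'   `spikes.csv` and `trials.csv`.
#' @param dir optional directory shorthand.
#' @param config `av_config` for the epoch bounds.
#' @return An `av_session`.
#' @export
read_session <- function(spike_path = NULL, trial_path = NULL, dir = NULL,
                         config = session_config()) {
  if (!is.null(dir)) {
    spike_path <- spike_path %||% file.path(dir, "spikes.csv")
    trial_path <- trial_path %||% file.path(dir, "trials.csv")
  }
  for (p in c(spike_path, trial_path)) {
    if (!file.exists(p)) {
      abort(paste0("file not found: ", p), class = "avspike_io_error")
    }
  }
  spikes_raw <- readr::read_csv(spike_path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  trials_raw <- readr::read_csv(trial_path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing_s <- setdiff(c("neuron_id", "trial_id", "spike_time_ms"),
                       names(spikes_raw))
  if (length(missing_s)) {
    abort(paste0("spike file is missing column(s): ",
                 paste(missing_s, collapse = ", ")),
          class = "avspike_schema_error")
  }
  missing_t <- setdiff(c("trial_id", "cue", "choice", "correct",
                         "reaction_time_ms"), names(trials_raw))
  if (length(missing_t)) {
    abort(paste0("trial file is missing column(s): ",
                 paste(missing_t, collapse = ", ")),
          class = "avspike_schema_error")
  }
  spikes <- tibble::tibble(
    neuron_id = spikes_raw$neuron_id,
    trial_id = as.integer(convert_numeric_column(spikes_raw, "trial_id",
                                                 spike_path)),
    spike_time_ms = convert_numeric_column(spikes_raw, "spike_time_ms",
                                           spike_path))
  trials <- tibble::tibble(
    trial_id = as.integer(convert_numeric_column(trials_raw, "trial_id",
                                                 trial_path)),
    cue = trials_raw$cue,
    choice = trials_raw$choice,
    correct = trials_raw$correct,
    reaction_time_ms = convert_numeric_column(trials_raw, "reaction_time_ms",
                                              trial_path))
  av_session(spikes, trials, config = config)
}

#' Write a session to delimited text files
#'
#' Writes `spikes.csv` and `trials.csv` (and `truth.json` when generator
#' ground truth is attached) such that [read_session()] recovers the tables
#' field-for-field. Missing reaction times are written as empty fields.
#'
#' @param session an `av_session`.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "av_session"))
  # re-validate: sessions assembled by hand must not serialise invalid state
  trials <- validate_trial_table(session$trials)
  spikes <- validate_spike_table(session$spikes, trials, session$config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(spikes = file.path(dir, "spikes.csv"),
             trials = file.path(dir, "trials.csv"))
  readr::write_csv(spikes, paths[["spikes"]], na = "", progress = FALSE)
  readr::write_csv(trials, paths[["trials"]], na = "", progress = FALSE)
  if (!is.null(session$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    jsonlite::write_json(session$truth, paths[["truth"]], digits = NA,
                         dataframe = "columns")
  }
  invisible(paths)
}
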