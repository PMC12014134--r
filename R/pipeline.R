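#' Run the full analysis pipeline on a synthetic or stored session
#'
#' Orchestrates generate/read -> activity screen -> responsiveness ->
#' selectivity -> MSI -> additivity -> decoding -> report, writing each
#' stage's table as CSV/JSON under `out_dir` together with a run manifest
#' (configuration snapshot, per-stage derived sub-seeds, row counts and
#' timings, package version). Every stochastic stage consumes its own
#' sub-seed derived from the master seed by a fixed counter scheme, so a
#' stage can be re-run in isolation and a re-run with the same seed
#' reproduces identical artifacts.
#'
#' @param out_dir output directory (created if needed).
#' @param config `av_config`.
#' @param seed master seed.
#' @param session optional existing `av_session`; by default a synthetic
#'   session is generated from `preset`.
#' @param preset preset name for [preset_scenario()].
#' @param n_neurons,trials_per_cue generator sizes when synthesising.
#' @param stages stages to run (subset of the default vector; `synth` is
#'   implied when no `session` is given). Stages absent from the vector are
#'   skipped and noted in the manifest.
#' @param decoding_contrast cue pair decoded in the `decoding` stage.
#' @return The manifest (list), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(out_dir, config = session_config(), seed = 1,
                         session = NULL, preset = "trained_right_AC",
                         n_neurons = 50, trials_per_cue = 40,
                         stages = c("responsiveness", "selectivity", "msi",
                                    "additivity", "decoding", "report"),
                         decoding_contrast = c("A3k", "A10k")) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package = "avspike",
                   version = as.character(utils::packageVersion("avspike")),
                   seed = as.integer(seed),
                   preset = if (is.null(session)) preset else NA,
                   config = unclass(config),
                   stages = list(), skipped = setdiff(
                     c("responsiveness", "selectivity", "msi", "additivity",
                       "decoding", "report"), stages))
  paths <- character()
  stage_seed <- function(k) derive_seed(seed, k)
  run_stage <- function(name, k, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- fun(stage_seed(k))
    manifest$stages[[name]] <<- list(seed = stage_seed(k),
                                     seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }
  write_tbl <- function(tbl, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tbl, p, na = "", progress = FALSE)
    paths <<- c(paths, setNames(p, name))
    manifest$rows[[name]] <<- nrow(tbl)
  }

  if (is.null(session)) {
    session <- run_stage("synth", 1L, function(s) {
      sc <- preset_scenario(preset, n_neurons = n_neurons,
                           trials_per_cue = trials_per_cue)
      generate_session(sc$pop, sc$behavior, config, seed = s)
    })
  }
  sp <- write_session(session, out_dir)
  paths <- c(paths, sp)
  manifest$n_trials <- nrow(session$trials)
  manifest$n_spikes <- nrow(session$spikes)
  manifest$n_neurons <- dplyr::n_distinct(session$spikes$neuron_id)

  act <- active_neurons(session$spikes, session$trials, config)
  keep <- act$neuron_id[act$active]
  spikes <- session$spikes[session$spikes$neuron_id %in% keep, , drop = FALSE]
  trials <- session$trials
  manifest$n_active_neurons <- length(keep)

  if ("responsiveness" %in% stages) {
    resp <- run_stage("responsiveness", 2L, function(s) {
      classify_responsiveness(spikes, trials, config)
    })
    write_tbl(resp, "responsiveness")
    write_tbl(categorize_neurons(resp), "categories")
  }
  if ("selectivity" %in% stages) {
    sel <- run_stage("selectivity", 3L, function(s) {
      purrr::imap_dfr(list(auditory = c("A10k", "A3k"),
                           visual = c("Vvt", "Vhz"),
                           multisensory = c("A10kVvt", "A3kVhz")),
                      function(cs, nm) {
        out <- selectivity_index(spikes, trials, cs[1], cs[2],
                                 config = config, seed = s)
        out$contrast <- nm
        out
      })
    })
    write_tbl(sel, "selectivity")
  }
  if ("msi" %in% stages) {
    msi_tbl <- run_stage("msi", 4L, function(s) {
      purrr::map_dfr(c("A10kVvt", "A3kVhz"), function(p) {
        msi(spikes, trials, p, config = config, seed = s)
      })
    })
    write_tbl(msi_tbl, "msi")
  }
  if ("additivity" %in% stages) {
    add_tbl <- run_stage("additivity", 5L, function(s) {
      add <- additivity_test(spikes, trials, "A10kVvt", config = config,
                             seed = s)
      ch <- scaling_coefficient(spikes, trials, "A10kVvt", config = config)
      dplyr::left_join(add, ch[c("neuron_id", "c_hat")], by = "neuron_id")
    })
    write_tbl(add_tbl, "additivity")
  }
  if ("decoding" %in% stages) {
    dec <- run_stage("decoding", 6L, function(s) {
      decode_timecourse(
        av_session(spikes, trials, config = config),
        decoding_contrast[1], decoding_contrast[2], config, seed = s)
    })
    write_tbl(dec$windows, "decoding")
    manifest$stages$decoding$null <- dec$null
  }
  if ("report" %in% stages) {
    rep_obj <- run_stage("report", 7L, function(s) {
      population_report(spikes, trials, config, seed = s)
    })
    rp <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(category_counts = rep_obj$category_counts,
           selectivity_counts = rep_obj$selectivity_counts,
           msi_counts = rep_obj$msi_counts,
           behavior_correct_rate = rep_obj$behavior$correct_rate,
           behavior_reaction_time = rep_obj$behavior$reaction_time),
      rp, dataframe = "columns", digits = NA, na = "null")
    paths <- c(paths, report = rp)
  }
  manifest$artifacts <- as.list(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  invisible(manifest)
}
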