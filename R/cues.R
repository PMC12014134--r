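#' Cue catalogue for the audiovisual discrimination task
#'
#' The task uses six target cues — two pure tones (`A3k`, `A10k`), two light
#' bars (`Vhz`, `Vvt`) and their trained pairings (`A3kVhz`, `A10kVvt`) — plus
#' two "unmatched" pairings (`A10kVhz`, `A3kVvt`) whose components indicate
#' opposite reward ports (either port may be rewarded on those trials).
#'
#' @return A tibble with one row per cue: `cue`, `modality`
#'   (auditory/visual/multisensory), `auditory_component`, `visual_component`,
#'   `reward_side` (left/right/either) and `matched` (for multisensory cues,
#'   whether both components indicate the same port).
#' @export
#' @examples
#' av_cue_table()
av_cue_table <- function() {
  tibble::tibble(
    cue = c("A3k", "A10k", "Vhz", "Vvt", "A3kVhz", "A10kVvt", "A10kVhz", "A3kVvt"),
    modality = c("auditory", "auditory", "visual", "visual",
                 rep("multisensory", 4)),
    auditory_component = c("A3k", "A10k", NA, NA, "A3k", "A10k", "A10k", "A3k"),
    visual_component = c(NA, NA, "Vhz", "Vvt", "Vhz", "Vvt", "Vhz", "Vvt"),
    reward_side = c("right", "left", "right", "left",
                    "right", "left", "either", "either"),
    matched = c(NA, NA, NA, NA, TRUE, TRUE, FALSE, FALSE)
  )
}

#' @rdname av_cue_table
#' @param modality optional filter: "auditory", "visual" or "multisensory".
#' @export
av_cues <- function(modality = NULL) {
  tbl <- av_cue_table()
  if (!is.null(modality)) tbl <- tbl[tbl$modality %in% modality, ]
  tbl$cue
}

cue_info <- function(cue) {
  tbl <- av_cue_table()
  i <- match(cue, tbl$cue)
  if (anyNA(i)) {
    abort(paste0("unknown cue(s): ", paste(cue[is.na(i)], collapse = ", ")),
          class = "avspike_validation_error")
  }
  tbl[i, ]
}

# trials usable for response analyses of a given cue: correct choices, plus
# all trials of unmatched cues (either port is rewarded there, so
# correctness is undefined and no trial is excluded)
usable_trials <- function(trials, cue, correct_only = TRUE) {
  out <- trials[trials$cue == cue, , drop = FALSE]
  if (correct_only) out <- out[out$correct %in% c("yes", "either"), , drop = FALSE]
  out
}
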