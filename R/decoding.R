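#' Assemble a pseudo-population response array for two cue classes
#'
#' Neurons from one or more sessions are combined into a single
#' pseudo-population: a neuron is eligible when it has at least
#' `min_trials` usable (correct) trials of each class; for each eligible
#' neuron `trials_per_cue` trials per class are drawn without replacement
#' in random order, so the pairing of trials across neurons is random
#' within class. Spike counts are taken in sliding windows (default 100 ms
#' stepped by 10 ms) over the decoding range, giving an M x N x T array
#' (pseudo-trials x neurons x windows).
#'
#' @param sessions an `av_session` or list of them.
#' @param class_a,class_b the two cue classes to decode.
#' @param config `av_config`; decoding parameters under `config$decoding`.
#' @param seed optional seed for the trial draws.
#' @return An object of class `av_pseudopop`: `x` (M x N x T count array),
#'   `y` (class factor of length M), `windows` (tibble of window starts and
#'   centers), `neurons` (session/neuron provenance) and `provenance`
#'   (M x N matrix of source trial ids).
#' @export
build_pseudopopulation <- function(sessions, class_a, class_b,
                                   config = session_config(), seed = NULL) {
  if (inherits(sessions, "av_session")) sessions <- list(sessions)
  dec <- config$decoding
  k <- dec$window_ms / dec$step_ms
  if (abs(k - round(k)) > 1e-9) {
    abort("decoding window_ms must be a multiple of step_ms",
          class = "avspike_validation_error")
  }
  k <- as.integer(round(k))
  range <- dec$range_ms %||% config$epoch
  edges <- seq(range[1], range[2], by = dec$step_ms)
  nbin <- length(edges) - 1
  nwin <- nbin - k + 1
  if (nwin < 1) {
    abort("decoding range shorter than one window",
          class = "avspike_validation_error")
  }
  starts <- edges[seq_len(nwin)]
  n_t <- as.integer(dec$trials_per_cue)
  with_seed_if(seed, {
    picks <- list()
    for (si in seq_along(sessions)) {
      s <- sessions[[si]]
      tr_a <- usable_trials(s$trials, class_a, TRUE)
      tr_b <- usable_trials(s$trials, class_b, TRUE)
      for (cls in list(c(class_a, nrow(tr_a)), c(class_b, nrow(tr_b)))) {
        if (as.integer(cls[2]) == 0) {
          abort(paste0("cue ", cls[1], " missing from session ", si),
                class = "avspike_validation_error")
        }
      }
      if (nrow(tr_a) < dec$min_trials || nrow(tr_b) < dec$min_trials) next
      for (nn in sort(unique(s$spikes$neuron_id))) {
        picks[[length(picks) + 1]] <- list(
          session = si, neuron = nn,
          a = sample(tr_a$trial_id, n_t),
          b = sample(tr_b$trial_id, n_t))
      }
    }
    if (length(picks) == 0) {
      abort(sprintf("no neuron has >= %d usable trials for both classes",
                    as.integer(dec$min_trials)),
            class = "avspike_validation_error")
    }
    m <- 2L * n_t
    n_neur <- length(picks)
    x <- array(0, dim = c(m, n_neur, nwin))
    prov <- matrix(NA_integer_, m, n_neur)
    for (j in seq_len(n_neur)) {
      p <- picks[[j]]
      s <- sessions[[p$session]]
      ids <- c(p$a, p$b)
      prov[, j] <- ids
      spk <- s$spikes[s$spikes$neuron_id == p$neuron &
                        s$spikes$trial_id %in% ids &
                        s$spikes$spike_time_ms >= range[1] &
                        s$spikes$spike_time_ms < range[2], , drop = FALSE]
      bins <- matrix(0L, m, nbin)
      if (nrow(spk) > 0) {
        row <- match(spk$trial_id, ids)
        col <- floor((spk$spike_time_ms - range[1]) / dec$step_ms) + 1
        for (i in seq_along(row)) bins[row[i], col[i]] <- bins[row[i], col[i]] + 1L
      }
      cum <- if (nbin > 1) t(apply(bins, 1, cumsum)) else bins
      cs <- cbind(0L, cum)
      x[, j, ] <- cs[, (k + 1):(nbin + 1), drop = FALSE] -
        cs[, 1:nwin, drop = FALSE]
    }
    structure(list(
      x = x,
      y = factor(rep(c(class_a, class_b), each = n_t),
                 levels = c(class_a, class_b)),
      windows = tibble::tibble(start = starts,
                               center = starts + dec$window_ms / 2),
      neurons = tibble::tibble(
        session = vapply(picks, function(p) p$session, 0),
        neuron_id = vapply(picks, function(p) p$neuron, "")),
      provenance = prov), class = "av_pseudopop")
  })
}

#' @export
print.av_pseudopop <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<av_pseudopop> %d pseudo-trials x %d neurons x %d windows (%s vs %s)\n",
              d[1], d[2], d[3], levels(x$y)[1], levels(x$y)[2]))
  invisible(x)
}

# extract window w of the count array as an M x N matrix (robust to N = 1)
slice_window <- function(pop, w) {
  xm <- pop$x[, , w, drop = FALSE]
  dim(xm) <- dim(xm)[1:2]
  xm
}

# stratified fold assignment: each class spread evenly over folds
stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  id
}

# k-fold cross-validated accuracy of a linear-kernel SVM
svm_cv_accuracy <- function(xm, y, fold_id, cost) {
  hits <- 0L
  for (f in unique(fold_id)) {
    test <- fold_id == f
    fit <- tryCatch(
      e1071::svm(xm[!test, , drop = FALSE], y[!test], kernel = "linear",
                 cost = cost, scale = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) {
      # fall back to the training majority class (e.g. featureless folds)
      maj <- names(which.max(table(y[!test])))
      hits <- hits + sum(y[test] == maj)
    } else {
      hits <- hits + sum(predict(fit, xm[test, , drop = FALSE]) == y[test])
    }
  }
  hits / length(y)
}

#' Time-resolved pseudo-population decoding
#'
#' Trains and tests a linear-kernel support vector machine independently in
#' each sliding window, with stratified 10-fold cross-validation, on
#' pseudo-populations rebuilt (new trial draws and pairings) for each of
#' `resamples` repetitions; reports the mean and SD of accuracy across
#' repetitions per window. A shuffled-label null is computed at the most
#' informative window (the per-window nulls are equivalent for balanced
#' classes but far more costly): labels are shuffled `shuffles` times and
#' the 2.5-97.5% band of the resulting cross-validated accuracies is
#' reported as the chance band.
#'
#' @param sessions an `av_session` or list of them.
#' @param class_a,class_b the two cue classes to decode.
#' @param config `av_config`; `config$decoding` supplies `window_ms`,
#'   `step_ms`, `trials_per_cue`, `min_trials`, `folds`, `resamples`,
#'   `shuffles`, `cost` and the decoding `range_ms`.
#' @param seed optional seed covering trial draws, folds and shuffles.
#' @return An object of class `av_decoding`: `windows` (tibble with
#'   `center`, `accuracy`, `sd`), `null` (list: `window_center`, `mean`,
#'   `lower`, `upper`, `n_shuffles`), `params`. `tidy()` returns the
#'   window tibble, `glance()` a one-row summary, `autoplot()` draws the
#'   accuracy course with the chance band.
#' @export
decode_timecourse <- function(sessions, class_a, class_b,
                              config = session_config(), seed = NULL) {
  dec <- config$decoding
  with_seed_if(seed, {
    acc <- NULL
    last_pop <- NULL
    for (r in seq_len(dec$resamples)) {
      pop <- build_pseudopopulation(sessions, class_a, class_b, config)
      if (is.null(acc)) {
        acc <- matrix(NA_real_, dec$resamples, nrow(pop$windows))
      }
      fold_id <- stratified_folds(pop$y, dec$folds)
      acc[r, ] <- vapply(seq_len(nrow(pop$windows)), function(w) {
        svm_cv_accuracy(slice_window(pop, w), pop$y, fold_id, dec$cost)
      }, numeric(1))
      last_pop <- pop
    }
    mean_acc <- colMeans(acc)
    best_w <- which.max(mean_acc)
    null_acc <- vapply(seq_len(dec$shuffles), function(i) {
      yp <- sample(last_pop$y)
      svm_cv_accuracy(slice_window(last_pop, best_w), yp,
                      stratified_folds(yp, dec$folds), dec$cost)
    }, numeric(1))
    structure(list(
      windows = tibble::tibble(center = last_pop$windows$center,
                               accuracy = mean_acc,
                               sd = apply(acc, 2, sd)),
      null = list(window_center = last_pop$windows$center[best_w],
                  mean = mean(null_acc),
                  lower = unname(quantile(null_acc, 0.025)),
                  upper = unname(quantile(null_acc, 0.975)),
                  n_shuffles = as.integer(dec$shuffles)),
      params = c(list(class_a = class_a, class_b = class_b,
                      n_neurons = nrow(last_pop$neurons)), dec)),
      class = "av_decoding")
  })
}

#' @export
print.av_decoding <- function(x, ...) {
  cat(sprintf("<av_decoding> %s vs %s: %d windows, peak accuracy %.3f at %g ms\n",
              x$params$class_a, x$params$class_b, nrow(x$windows),
              max(x$windows$accuracy),
              x$windows$center[which.max(x$windows$accuracy)]))
  cat(sprintf("  chance band [%.3f, %.3f] (%d shuffles)\n",
              x$null$lower, x$null$upper, x$null$n_shuffles))
  invisible(x)
}

#' Earliest time a decoding curve reaches a target accuracy
#'
#' Returns the center of the earliest window whose mean accuracy reaches
#' `level` (no interpolation), or `NA` if the level is never reached.
#'
#' @param result an `av_decoding` object.
#' @param level accuracy fraction (default 0.9).
#' @return Window center in ms, or `NA_real_`.
#' @export
first_crossing_time <- function(result, level = 0.9) {
  stopifnot(inherits(result, "av_decoding"))
  idx <- which(result$windows$accuracy >= level)
  if (length(idx) == 0) NA_real_ else result$windows$center[idx[1]]
}

#' All-pairs cue decoding matrix in a single window
#'
#' Cross-validated decoding accuracy for every unordered pair from a cue
#' set, using counts in one window (default the 0-150 ms analysis window).
#' The matrix is symmetric with the diagonal fixed at 0.5 by convention.
#'
#' @param sessions an `av_session` or list of them.
#' @param cues cue set (default all 8).
#' @param window single counting window, ms.
#' @param config `av_config`; `resamples`, `folds`, `trials_per_cue`,
#'   `min_trials` and `cost` are taken from `config$decoding`.
#' @param seed optional seed.
#' @return An object of class `av_decoding_matrix`: `accuracy` (named
#'   square matrix), `window`, `n_resamples`. `tidy()` returns a long
#'   tibble; `autoplot()` draws the matrix.
#' @export
decoding_matrix <- function(sessions, cues = av_cues(), window = c(0, 150),
                            config = session_config(), seed = NULL) {
  if (inherits(sessions, "av_session")) sessions <- list(sessions)
  check_window(window)
  present <- unique(unlist(purrr::map(sessions, function(s) s$trials$cue)))
  missing <- setdiff(cues, present)
  if (length(missing)) {
    abort(paste0("cue(s) missing from the session(s): ",
                 paste(missing, collapse = ", ")),
          class = "avspike_validation_error")
  }
  cfg1 <- config
  cfg1$decoding$range_ms <- window
  cfg1$decoding$window_ms <- diff(window)
  cfg1$decoding$step_ms <- diff(window)
  dec <- cfg1$decoding
  n_cue <- length(cues)
  accm <- matrix(0.5, n_cue, n_cue, dimnames = list(cues, cues))
  with_seed_if(seed, {
    for (i in seq_len(n_cue - 1)) {
      for (j in (i + 1):n_cue) {
        accs <- vapply(seq_len(dec$resamples), function(r) {
          pop <- build_pseudopopulation(sessions, cues[i], cues[j], cfg1)
          fold_id <- stratified_folds(pop$y, dec$folds)
          svm_cv_accuracy(slice_window(pop, 1), pop$y, fold_id, dec$cost)
        }, numeric(1))
        accm[i, j] <- accm[j, i] <- mean(accs)
      }
    }
  })
  structure(list(accuracy = accm, window = window,
                 n_resamples = as.integer(dec$resamples)),
            class = "av_decoding_matrix")
}

#' @export
print.av_decoding_matrix <- function(x, ...) {
  cat(sprintf("<av_decoding_matrix> %d cues, window [%g, %g) ms\n",
              nrow(x$accuracy), x$window[1], x$window[2]))
  print(round(x$accuracy, 3))
  invisible(x)
}
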