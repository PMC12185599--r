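# Trial selection, per-phase analysis windows, epoch extraction, and
# behavioral summaries.

#' Apply the trial-selection rules
#'
#' Removes trials whose Response-phase duration is shorter than 0.5 s (the
#' participant moved early) or longer than 3 s (inattention).  If fewer than
#' 50% of the run's trials survive, the whole run is flagged for discard; the
#' surviving trial ids are still returned so callers can inspect them.
#'
#' @param log a `session_log`.
#' @param min_response_s,max_response_s admissible Response duration bounds.
#' @return A list with `kept` (trial ids, original order) and `run_discarded`
#'   (logical).
#' @export
select_trials <- function(log, min_response_s = 0.5, max_response_s = 3) {
  if (nrow(log) == 0) stopf("empty session log")
  dur <- log$response_duration
  ok <- dur >= min_response_s & dur <= max_response_s
  kept <- log$trial_id[ok]
  list(kept = kept, run_discarded = length(kept) < 0.5 * nrow(log))
}

#' Default per-phase analysis windows
#'
#' The analysis extracts 0.5 s from each phase: at the start of Fixation and
#' Delay, 0.8 s into the ITI (so no residual movement is captured), the whole
#' 0.25 s Cue, and the final 0.5 s of the Response phase (anchored at the
#' touch that ends the phase, so movement is always inside the window).
#'
#' @return A data frame with columns `phase`, `anchor` (`"start"`/`"end"`),
#'   `offset_s`, `duration_s`.
#' @export
default_windows <- function() {
  data.frame(
    phase = task_phases(),
    anchor = c("start", "start", "start", "start", "end"),
    offset_s = c(0.8, 0, 0, 0, 0),
    duration_s = c(0.5, 0.5, 0.25, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Extract per-phase analysis epochs
#'
#' Cuts the analysis window of each phase out of every retained trial, with
#' onset-to-sample alignment by nearest-sample rounding.  Trials whose phase
#' is too short to contain the window are dropped for that phase only (this
#' can happen for the ITI, whose window needs 1.3 s while the phase may last
#' only 1 s) and recorded in the result.
#'
#' @param rec a `seeg_recording`.
#' @param log the matching `session_log`.
#' @param kept trial ids retained by [select_trials()]; defaults to all.
#' @param windows analysis windows, see [default_windows()].
#' @return A `phase_epochs` object: per phase a list with `trials` (ids),
#'   `dropped` (ids whose phase could not fit the window), `data` (array
#'   trials x samples x channels, microvolt), plus `fs` and `contacts`.
#' @export
extract_phase_epochs <- function(rec, log, kept = log$trial_id,
                                 windows = default_windows()) {
  if (length(kept) == 0) stopf("empty-epochs: no kept trials to extract")
  fs <- rec$fs
  n_total <- nrow(rec$samples)
  phases <- list()
  for (r in seq_len(nrow(windows))) {
    ph <- windows$phase[r]
    win_len <- as.integer(round(windows$duration_s[r] * fs))
    iv <- phase_intervals(log, ph)
    iv <- iv[iv$trial_id %in% kept, , drop = FALSE]
    need <- windows$offset_s[r] + windows$duration_s[r]
    fits <- iv$duration >= need - 1e-9
    use <- iv[fits, , drop = FALSE]
    if (nrow(use) == 0) {
      stopf("empty-epochs: the %s window (%.2f s) exceeds the phase duration for every kept trial",
            ph, need)
    }
    start_s <- if (windows$anchor[r] == "end") {
      use$onset + use$duration - windows$offset_s[r] - windows$duration_s[r]
    } else {
      use$onset + windows$offset_s[r]
    }
    i0 <- round(start_s * fs) + 1L
    arr <- array(0, dim = c(nrow(use), win_len, ncol(rec$samples)))
    for (k in seq_len(nrow(use))) {
      sel <- i0[k]:(i0[k] + win_len - 1L)
      if (sel[length(sel)] > n_total || sel[1] < 1) {
        stopf("epoch window for trial %d (%s) falls outside the recording",
              use$trial_id[k], ph)
      }
      arr[k, , ] <- rec$samples[sel, , drop = FALSE]
    }
    phases[[ph]] <- list(trials = use$trial_id,
                         dropped = iv$trial_id[!fits],
                         start_s = start_s,
                         duration_s = windows$duration_s[r],
                         data = arr)
  }
  structure(list(phases = phases, fs = fs, contacts = rec$contacts,
                 windows = windows),
            class = "phase_epochs")
}

#' Epochs of a single channel in one phase
#'
#' @param epochs a `phase_epochs` object.
#' @param phase phase name.
#' @param contact_id a contact id present in the epoch metadata.
#' @return A trials x samples matrix.
#' @export
channel_epochs <- function(epochs, phase, contact_id) {
  ph <- epochs$phases[[phase]]
  if (is.null(ph)) stopf("phase %s not present in epochs", phase)
  j <- match(contact_id, epochs$contacts$contact_id)
  if (is.na(j)) stopf("unknown contact id %s", contact_id)
  m <- ph$data[, , j, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  rownames(m) <- ph$trials
  m
}

#' Behavioral performance summary
#'
#' Successful trials are those flagged correct whose response time is
#' strictly below 5 s.  The success rate is the percentage of successful
#' trials; mean delay, movement and trial times are computed over successful
#' trials only.  Trial time runs from ITI onset to the end of the Response
#' phase.
#'
#' @param log a `session_log`.
#' @return A `behavior_summary` list with `success_rate` (percent),
#'   `mean_delay_time`, `mean_movement_time`, `mean_trial_time` (s),
#'   `total_trials` and `trials_after_outlier_removal` (filled downstream,
#'   `NA` here).
#' @export
compute_behavior <- function(log) {
  if (nrow(log) == 0) stopf("empty session log")
  good <- log$success & log$response_time < 5
  rate <- 100 * sum(good) / nrow(log)
  if (!any(good)) {
    out <- list(success_rate = 0, mean_delay_time = NA_real_,
                mean_movement_time = NA_real_, mean_trial_time = NA_real_,
                total_trials = nrow(log),
                trials_after_outlier_removal = NA_integer_)
  } else {
    g <- log[good, , drop = FALSE]
    trial_time <- g$response_onset + g$response_duration - g$iti_onset
    out <- list(
      success_rate = rate,
      mean_delay_time = mean(g$delay_duration),
      mean_movement_time = mean(g$response_time),
      mean_trial_time = mean(trial_time),
      total_trials = nrow(log),
      trials_after_outlier_removal = NA_integer_
    )
  }
  class(out) <- "behavior_summary"
  out
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("Behavior: %d trials, success rate %.2f%%\n",
              x$total_trials, x$success_rate))
  cat(sprintf("  mean delay %.2f s, movement %.2f s, trial %.2f s\n",
              x$mean_delay_time, x$mean_movement_time, x$mean_trial_time))
  invisible(x)
}
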