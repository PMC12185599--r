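#' Generate a session log for a delayed-reach run
#'
#' Draws per-trial phase durations from the task template (ITI uniform on
#' 1--2 s, Fixation 1--4 s, Cue fixed 0.25 s, Delay 2--4 s, Response from a
#' truncated normal clipped to `(0, 2]`), assigns reach targets over the eight
#' directions (balanced whenever `n_trials` is divisible by 8), and lays the
#' phases out contiguously so that trial onsets are strictly increasing.
#'
#' @param spec a [cohort_spec()].
#' @param rng_seed integer seed for this run's randomness.
#' @param participant_id identifier stored with the log.
#' @return A `session_log`: a data frame with one row per trial and columns
#'   `trial_id`, `target_index` (0--7), `response_time` (s), `success`, and
#'   `<phase>_onset` / `<phase>_duration` (s) for the five phases.
#' @export
make_session_log <- function(spec, rng_seed = spec$seed,
                             participant_id = "p01") {
  validate_cohort_spec(spec)
  n <- spec$n_trials
  if (!is_count(n)) stopf("invalid spec: n_trials must be a positive count")
  with_seed(rng_seed, {
    iti <- runif(n, 1, 2)
    fixation <- runif(n, 1, 4)
    cue <- rep(0.25, n)
    delay <- runif(n, 2, 4)
    response <- rtruncnorm_clipped(n, spec$response_mean, spec$response_sd,
                                   lo = 0, hi = 2)
    target <- draw_targets(n)
    success <- runif(n) < spec$p_success
    durs <- cbind(ITI = iti, Fixation = fixation, Cue = cue,
                  Delay = delay, Response = response)
    trial_len <- rowSums(durs)
    trial_start <- cumsum(c(0, trial_len[-n]))
    onsets <- trial_start + cbind(0, iti, iti + fixation, iti + fixation + cue,
                                  iti + fixation + cue + delay)
    colnames(onsets) <- task_phases()
    log <- data.frame(
      trial_id = seq_len(n),
      target_index = target,
      response_time = response,
      success = success
    )
    for (ph in task_phases()) {
      log[[paste0(tolower(ph), "_onset")]] <- onsets[, ph]
      log[[paste0(tolower(ph), "_duration")]] <- durs[, ph]
    }
    attr(log, "participant_id") <- participant_id
    attr(log, "handedness") <- "right"
    class(log) <- c("session_log", "data.frame")
    log
  })
}

# Truncated normal via inverse-CDF sampling on the admissible quantile range;
# the lower bound is open so exact zeros cannot occur.
rtruncnorm_clipped <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  u <- runif(n, plo, phi)
  x <- qnorm(u, mean, sd)
  pmin(pmax(x, lo + 1e-9), hi)
}

# Balanced assignment over 8 reach directions when possible: each direction
# appears floor(n/8) times, the remainder is drawn without replacement.
draw_targets <- function(n) {
  base <- rep(0:7, n %/% 8)
  extra <- if (n %% 8 > 0) sample(0:7, n %% 8) else integer(0)
  sample(c(base, extra))
}

#' Onset and duration of one phase across trials
#'
#' @param log a `session_log`.
#' @param phase one of `"ITI"`, `"Fixation"`, `"Cue"`, `"Delay"`,
#'   `"Response"`.
#' @return A data frame with columns `trial_id`, `onset`, `duration`.
#' @export
phase_intervals <- function(log, phase) {
  phase <- match.arg(phase, task_phases())
  data.frame(
    trial_id = log$trial_id,
    onset = log[[paste0(tolower(phase), "_onset")]],
    duration = log[[paste0(tolower(phase), "_duration")]]
  )
}

session_duration <- function(log) {
  n <- nrow(log)
  log$response_onset[n] + log$response_duration[n]
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("Session log: %d trials, participant %s, %.1f s total\n",
              nrow(x), attr(x, "participant_id") %||% "?",
              session_duration(x)))
  NextMethod()
}
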