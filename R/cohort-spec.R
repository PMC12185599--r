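#' Specify a synthetic SEEG cohort
#'
#' Builds the parameter set that drives the synthetic stereo-EEG generator.
#' The defaults emulate a delayed-reach center-out study: eleven participants
#' with bilateral depth-electrode shafts, 2000 Hz acquisition, 64 trials per
#' run split into the five task phases (ITI, Fixation, Cue, Delay, Response),
#' 60 Hz line contamination with drifting amplitude, sporadic interictal
#' spikes, a power-law background, and a beta-band (13--30 Hz) oscillation
#' whose power drops during the Delay and Response phases on designated
#' gray-matter contacts.
#'
#' @param n_participants number of simulated participants.
#' @param shafts_per_participant electrode shafts per participant; with the
#'   default 2, one shaft is placed in each hemisphere.
#' @param contacts_per_shaft contacts along each shaft.
#' @param fs sampling rate in Hz.
#' @param n_trials trials per run.
#' @param gray_fraction fraction of contacts on each shaft labelled gray
#'   matter (the deepest contacts).
#' @param erd_fraction_of_gray fraction of gray-matter contacts carrying
#'   event-related desynchronization (ERD).
#' @param erd_power_drop fractional beta-power drop in `[0, 1)` applied during
#'   Delay and Response on ERD contacts (the beta power multiplier is
#'   `1 - erd_power_drop`).
#' @param beta_center,beta_bandwidth center frequency and full bandwidth (Hz)
#'   of the beta oscillation.
#' @param beta_amp_gray,beta_amp_white beta-component RMS amplitude (microvolt)
#'   for gray and white matter contacts.
#' @param background_amp_gray,background_amp_white RMS amplitude (microvolt)
#'   of the aperiodic background per tissue class.
#' @param background_exponent spectral exponent of the background power
#'   spectral density (PSD proportional to `1/f^exponent`).
#' @param shaft_common_amp RMS amplitude (microvolt) of the common component
#'   shared by all contacts of a shaft.
#' @param line_amp line-noise amplitude (microvolt, sinusoid peak) at the
#'   fundamental; harmonic `k` is scaled by `1/k`.
#' @param line_harmonics number of line harmonics (including the fundamental).
#' @param spike_rate interictal spike rate (events per minute) on spiky
#'   channels.
#' @param spiky_channel_fraction fraction of contacts that carry spikes.
#' @param p_success per-trial probability of a behaviorally successful trial.
#' @param response_mean,response_sd mean and standard deviation (s) of the
#'   truncated-normal Response-phase duration, clipped to `(0, 2]`.
#' @param beta_mode `"narrowband"` for band-limited filtered noise (default,
#'   physiological-looking spectra) or `"tone"` for a pure sinusoid at
#'   `beta_center` (useful as a spectral oracle).
#' @param seed master integer seed; all per-participant randomness is derived
#'   deterministically from it.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [make_session_log()], [synthesize_recording()], [make_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(n_participants = 1, n_trials = 8, seed = 42)
#' log <- make_session_log(spec, rng_seed = 1)
#' table(log$target_index)
cohort_spec <- function(n_participants = 11,
                        shafts_per_participant = 2,
                        contacts_per_shaft = 8,
                        fs = 2000,
                        n_trials = 64,
                        gray_fraction = 0.625,
                        erd_fraction_of_gray = 0.5,
                        erd_power_drop = 0.3,
                        beta_center = 21,
                        beta_bandwidth = 10,
                        beta_amp_gray = 10,
                        beta_amp_white = 3,
                        background_amp_gray = 40,
                        background_amp_white = 10,
                        background_exponent = 2,
                        shaft_common_amp = 20,
                        line_amp = 20,
                        line_harmonics = 3,
                        spike_rate = 2,
                        spiky_channel_fraction = 0.25,
                        p_success = 0.9,
                        response_mean = 1.47,
                        response_sd = 0.21,
                        beta_mode = c("narrowband", "tone"),
                        seed = 1L) {
  beta_mode <- match.arg(beta_mode)
  spec <- list(
    n_participants = n_participants,
    shafts_per_participant = shafts_per_participant,
    contacts_per_shaft = contacts_per_shaft,
    fs = fs, n_trials = n_trials,
    gray_fraction = gray_fraction,
    erd_fraction_of_gray = erd_fraction_of_gray,
    erd_power_drop = erd_power_drop,
    beta_center = beta_center, beta_bandwidth = beta_bandwidth,
    beta_amp_gray = beta_amp_gray, beta_amp_white = beta_amp_white,
    background_amp_gray = background_amp_gray,
    background_amp_white = background_amp_white,
    background_exponent = background_exponent,
    shaft_common_amp = shaft_common_amp,
    line_amp = line_amp, line_harmonics = line_harmonics,
    spike_rate = spike_rate,
    spiky_channel_fraction = spiky_channel_fraction,
    p_success = p_success,
    response_mean = response_mean, response_sd = response_sd,
    beta_mode = beta_mode,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (!is_count(spec$n_participants)) stopf("invalid spec: n_participants must be a positive count")
  if (!is_count(spec$shafts_per_participant)) stopf("invalid spec: shafts_per_participant must be a positive count")
  if (!is_count(spec$contacts_per_shaft)) stopf("invalid spec: contacts_per_shaft must be a positive count")
  if (!is_count(spec$n_trials)) stopf("invalid spec: n_trials must be a positive count")
  if (!is_number(spec$fs) || spec$fs <= 0) stopf("invalid spec: fs must be positive")
  amps <- c(spec$beta_amp_gray, spec$beta_amp_white, spec$background_amp_gray,
            spec$background_amp_white, spec$shaft_common_amp, spec$line_amp)
  if (any(!vapply(amps, is_number, logical(1))) || any(amps < 0)) {
    stopf("invalid spec: all amplitudes must be non-negative numbers")
  }
  if (!is_number(spec$erd_power_drop) || spec$erd_power_drop < 0 ||
      spec$erd_power_drop >= 1) {
    stopf("invalid spec: erd_power_drop must lie in [0, 1)")
  }
  if (!is_number(spec$gray_fraction) || spec$gray_fraction <= 0 ||
      spec$gray_fraction > 1) {
    stopf("invalid spec: gray_fraction must lie in (0, 1]")
  }
  if (spec$erd_fraction_of_gray < 0 || spec$erd_fraction_of_gray > 1) {
    stopf("invalid spec: erd_fraction_of_gray must lie in [0, 1]")
  }
  if (spec$spiky_channel_fraction < 0 || spec$spiky_channel_fraction > 1) {
    stopf("invalid spec: spiky_channel_fraction must lie in [0, 1]")
  }
  if (spec$line_harmonics < 0) stopf("invalid spec: line_harmonics must be >= 0")
  if (spec$line_harmonics >= 1 &&
      spec$line_harmonics * 60 >= spec$fs / 2) {
    stopf("invalid spec: highest line harmonic reaches the Nyquist frequency")
  }
  invisible(spec)
}

#' Phase-duration template of the delayed-reach task
#'
#' The five task phases and their duration ranges in seconds: ITI 1--2 s,
#' Fixation 1--4 s, Cue fixed at 0.25 s, Delay 2--4 s, Response at most 2 s
#' (drawn from a truncated normal; see [cohort_spec()]).
#'
#' @return A data frame with columns `phase`, `min_s`, `max_s`.
#' @export
phase_template <- function() {
  data.frame(
    phase = task_phases(),
    min_s = c(1, 1, 0.25, 2, 0),
    max_s = c(2, 4, 0.25, 4, 2),
    stringsAsFactors = FALSE
  )
}

#' A noise-free cohort configuration for spectral oracle checks
#'
#' Returns a [cohort_spec()] in which the aperiodic background, the
#' shaft-common component, line noise and spikes are suppressed (or nearly so)
#' and only the beta oscillation remains.  In this regime the in-band power
#' ratio between phases directly reflects the programmed ERD multiplier,
#' which makes the configuration suitable for quantitative recovery checks of
#' the spectral pipeline.
#'
#' @param ... overrides passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
erd_oracle_spec <- function(...) {
  args <- list(
    n_participants = 1, shafts_per_participant = 1, contacts_per_shaft = 2,
    gray_fraction = 1, erd_fraction_of_gray = 0.5, erd_power_drop = 0.5,
    beta_amp_gray = 15, beta_amp_white = 15,
    background_amp_gray = 1, background_amp_white = 1,
    shaft_common_amp = 0, line_amp = 0, spike_rate = 0,
    spiky_channel_fraction = 0, seed = 7L
  )
  user <- list(...)
  args[names(user)] <- user
  do.call(cohort_spec, args)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic SEEG cohort specification\n")
  cat(sprintf("  %d participant(s), %d shaft(s) x %d contacts, fs = %g Hz\n",
              x$n_participants, x$shafts_per_participant,
              x$contacts_per_shaft, x$fs))
  cat(sprintf("  %d trials; beta %g Hz (bw %g Hz, %s), ERD drop %.2f on %.0f%% of gray contacts\n",
              x$n_trials, x$beta_center, x$beta_bandwidth, x$beta_mode,
              x$erd_power_drop, 100 * x$erd_fraction_of_gray))
  cat(sprintf("  line %g uV x %d harmonic(s); spikes %g/min on %.0f%% of contacts; seed %d\n",
              x$line_amp, x$line_harmonics, x$spike_rate,
              100 * x$spiky_channel_fraction, x$seed))
  invisible(x)
}
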