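# Synthetic SEEG signal generation with known ground truth.

# Gaussian noise spectrally shaped so that the PSD falls as 1/f^exponent,
# with a plateau below f_lo (emulating the acquisition high-pass corner) and
# exact RMS normalization.
colored_noise <- function(n, fs, rms, exponent = 2, f_lo = 0.3) {
  if (rms <= 0 || n < 2) return(numeric(n))
  ng <- stats::nextn(n, c(2, 3, 5))   # FFT-friendly length, then truncate
  w <- rnorm(ng)
  W <- fft(w)
  f <- c(0, seq_len(ng - 1)) * fs / ng
  f <- pmin(f, fs - f)            # two-sided frequency magnitude
  gain <- 1 / pmax(f, f_lo)^(exponent / 2)
  gain[1] <- 0                    # remove DC
  x <- Re(fft(W * gain, inverse = TRUE))[seq_len(n)] / ng
  x * rms / stats::sd(x)
}

# Band-limited Gaussian noise via FFT masking with raised-cosine edges.
narrowband_noise <- function(n, fs, rms, center, bandwidth, edge = 2) {
  if (rms <= 0 || n < 2) return(numeric(n))
  ng <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(ng)
  W <- fft(w)
  f <- c(0, seq_len(ng - 1)) * fs / ng
  f <- pmin(f, fs - f)
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  gain <- numeric(ng)
  inside <- f >= lo & f <= hi
  gain[inside] <- 1
  ramp_lo <- f >= lo - edge & f < lo
  gain[ramp_lo] <- 0.5 * (1 + cos(pi * (lo - f[ramp_lo]) / edge))
  ramp_hi <- f > hi & f <= hi + edge
  gain[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - hi) / edge))
  x <- Re(fft(W * gain, inverse = TRUE))[seq_len(n)] / ng
  x * rms / stats::sd(x)
}

# Slow unit-variance drift process: white noise smoothed by a ~10 s moving
# average, so the drift bandwidth is on the order of 0.1 Hz.
slow_drift <- function(n, fs, window_s = 10) {
  half <- max(1L, as.integer(round(window_s * fs / 2)))
  d <- moving_average(rnorm(n), half)
  s <- stats::sd(d)
  if (s == 0) return(numeric(n))
  d / s
}

# 60 Hz line noise plus harmonics with slowly drifting amplitude and phase.
# Harmonic k has amplitude amp / k.
line_noise <- function(n, fs, amp, f0 = 60, n_harmonics = 3,
                       amp_drift = 0.2, phase_drift = 0.3) {
  if (amp <= 0 || n_harmonics < 1) return(numeric(n))
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (k in seq_len(n_harmonics)) {
    a <- (amp / k) * pmax(1 + amp_drift * slow_drift(n, fs), 0.05)
    ph <- phase_drift * slow_drift(n, fs) + runif(1, 0, 2 * pi)
    x <- x + a * sin(2 * pi * k * f0 * t + ph)
  }
  x
}

# Biphasic interictal-spike waveform: a sharp Mexican-hat transient (whose
# energy sits well above 30 Hz so the fixed-threshold detector can see it)
# followed by a slower after-wave.  Peak time is at `center_idx`.
spike_waveform <- function(fs, peak_uv, sharp_sd_s, total_s) {
  half <- as.integer(round(total_s * fs / 2))
  t <- (-half:half) / fs
  u <- t / sharp_sd_s
  sharp <- (1 - u^2) * exp(-u^2 / 2)
  slow <- numeric(length(t))
  after <- t > 0 & t <= total_s / 2
  slow[after] <- -0.35 * sin(pi * t[after] / (total_s / 2))
  w <- sharp + slow
  w * peak_uv / max(abs(w))
}

# Poisson spike times (rate per minute) with a refractory floor so injected
# events never merge into one detected excursion.
draw_spike_times <- function(duration_s, rate_per_min, min_gap = 0.5,
                             edge_pad = 0.5) {
  if (rate_per_min <= 0) return(numeric(0))
  rate_s <- rate_per_min / 60
  times <- numeric(0)
  t <- edge_pad
  repeat {
    t <- t + min_gap + rexp(1, rate_s)
    if (t > duration_s - edge_pad) break
    times <- c(times, t)
  }
  times
}

# Contact metadata table for one participant.  Shafts alternate hemispheres
# (left first); the deepest contacts on each shaft are gray matter; the task
# is right-handed, so left-hemisphere contacts are contralateral.
make_contacts <- function(spec, participant_id = "p01") {
  rows <- list()
  n_gray <- max(1L, round(spec$gray_fraction * spec$contacts_per_shaft))
  for (s in seq_len(spec$shafts_per_participant)) {
    hemi <- if (s %% 2 == 1) "left" else "right"
    for (ci in seq_len(spec$contacts_per_shaft)) {
      rows[[length(rows) + 1]] <- data.frame(
        contact_id = sprintf("%s_s%d_c%d", participant_id, s, ci),
        shaft_id = sprintf("%s_s%d", participant_id, s),
        index_on_shaft = ci - 1L,
        tissue = if (ci <= n_gray) "gray" else "white",
        hemisphere = hemi,
        laterality = if (hemi == "left") "contralateral" else "ipsilateral",
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Synthesize one SEEG recording with ground truth
#'
#' Generates a microvolt-calibrated multichannel recording for one simulated
#' participant.  Per contact the signal is the sum of: a tissue-scaled
#' power-law background, a component common to all contacts of the shaft,
#' drifting 60 Hz line noise plus harmonics, a band-limited beta oscillation
#' whose amplitude is multiplied by `sqrt(1 - erd_power_drop)` during the
#' Delay and Response phases on ERD contacts, and biphasic interictal spike
#' transients (peak 50--150 microvolt, 50--100 ms) on spiky contacts.
#'
#' @param spec a [cohort_spec()].
#' @param log a [make_session_log()] result for this run.
#' @param rng_seed integer seed for the signal randomness.
#' @param participant_id identifier used in contact/shaft names.
#' @param max_duration_s guard against absurdly long sessions.
#' @return A list with elements `recording` (class `seeg_recording`: `samples`
#'   time x channels in microvolt, `fs`, `contacts` metadata) and `truth`
#'   (class `ground_truth`: `erd_contacts`, `spiky_contacts`, `spike_times`
#'   per contact, and `phase_beta_gain`, the per-phase beta power multiplier
#'   per contact).
#' @export
synthesize_recording <- function(spec, log, rng_seed = spec$seed,
                                 participant_id = "p01",
                                 max_duration_s = 3600) {
  validate_cohort_spec(spec)
  dur <- session_duration(log) + 1
  if (dur > max_duration_s) {
    stopf("invalid spec: session duration %.0f s exceeds the %.0f s limit",
          dur, max_duration_s)
  }
  fs <- spec$fs
  n <- as.integer(ceiling(dur * fs))
  contacts <- make_contacts(spec, participant_id)
  nc <- nrow(contacts)

  with_seed(rng_seed, {
    gray_ids <- contacts$contact_id[contacts$tissue == "gray"]
    n_erd <- round(spec$erd_fraction_of_gray * length(gray_ids))
    erd_ids <- if (n_erd > 0) sort(sample(gray_ids, n_erd)) else character(0)
    n_spiky <- if (spec$spike_rate > 0) round(spec$spiky_channel_fraction * nc) else 0L
    spiky_ids <- if (n_spiky > 0) sort(sample(contacts$contact_id, n_spiky)) else character(0)

    # Beta amplitude envelope shared by all ERD contacts: the multiplier is
    # sqrt(1 - drop) inside Delay and Response, 1 elsewhere.
    erd_env <- rep(1, n)
    if (spec$erd_power_drop > 0) {
      g <- sqrt(1 - spec$erd_power_drop)
      for (ph in c("Delay", "Response")) {
        iv <- phase_intervals(log, ph)
        for (r in seq_len(nrow(iv))) {
          i0 <- max(1L, round(iv$onset[r] * fs) + 1L)
          i1 <- min(n, round((iv$onset[r] + iv$duration[r]) * fs))
          if (i1 >= i0) erd_env[i0:i1] <- g
        }
      }
    }

    t <- (seq_len(n) - 1) / fs
    samples <- matrix(0, n, nc)
    colnames(samples) <- contacts$contact_id
    shaft_ids <- unique(contacts$shaft_id)
    common <- lapply(shaft_ids, function(s) {
      colored_noise(n, fs, spec$shaft_common_amp, spec$background_exponent)
    })
    names(common) <- shaft_ids
    line <- line_noise(n, fs, spec$line_amp, 60, spec$line_harmonics)

    spike_times <- stats::setNames(vector("list", nc), contacts$contact_id)
    for (j in seq_len(nc)) {
      meta <- contacts[j, ]
      bg_amp <- if (meta$tissue == "gray") spec$background_amp_gray else spec$background_amp_white
      beta_amp <- if (meta$tissue == "gray") spec$beta_amp_gray else spec$beta_amp_white
      x <- colored_noise(n, fs, bg_amp, spec$background_exponent) +
        common[[meta$shaft_id]] + line
      if (beta_amp > 0) {
        beta <- if (spec$beta_mode == "tone") {
          sqrt(2) * beta_amp * sin(2 * pi * spec$beta_center * t + runif(1, 0, 2 * pi))
        } else {
          narrowband_noise(n, fs, beta_amp, spec$beta_center, spec$beta_bandwidth)
        }
        if (meta$contact_id %in% erd_ids) beta <- beta * erd_env
        x <- x + beta
      }
      st <- numeric(0)
      if (meta$contact_id %in% spiky_ids && spec$spike_rate > 0) {
        st <- draw_spike_times(dur, spec$spike_rate)
        for (s0 in st) {
          w <- spike_waveform(fs, peak_uv = runif(1, 50, 150),
                              sharp_sd_s = runif(1, 0.0035, 0.006),
                              total_s = runif(1, 0.05, 0.1))
          center <- as.integer(round(s0 * fs)) + 1L
          half <- (length(w) - 1L) %/% 2L
          i0 <- center - half
          i1 <- center + half
          sel <- i0:i1
          keep <- sel >= 1 & sel <= n
          x[sel[keep]] <- x[sel[keep]] + w[keep]
        }
      }
      spike_times[[meta$contact_id]] <- st
      samples[, j] <- x
    }

    gain <- stats::setNames(rep(1, nc), contacts$contact_id)
    gain[erd_ids] <- 1 - spec$erd_power_drop
    phase_beta_gain <- list(ITI = stats::setNames(rep(1, nc), contacts$contact_id),
                            Fixation = stats::setNames(rep(1, nc), contacts$contact_id),
                            Cue = stats::setNames(rep(1, nc), contacts$contact_id),
                            Delay = gain, Response = gain)

    recording <- structure(
      list(samples = samples, fs = fs, contacts = contacts,
           participant_id = participant_id),
      class = "seeg_recording"
    )
    truth <- structure(
      list(erd_contacts = erd_ids, spiky_contacts = spiky_ids,
           spike_times = spike_times, phase_beta_gain = phase_beta_gain),
      class = "ground_truth"
    )
    list(recording = recording, truth = truth)
  })
}

#' Generate a full synthetic cohort
#'
#' One (recording, session log, ground truth) triple per participant, each
#' driven by an independent child seed derived deterministically from
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A list of length `spec$n_participants`; each element has fields
#'   `recording`, `log`, `truth`, `participant_id`.
#' @export
make_cohort <- function(spec) {
  validate_cohort_spec(spec)
  lapply(seq_len(spec$n_participants), function(i) {
    simulate_participant(spec, i)
  })
}

#' Simulate a single cohort member
#'
#' @param spec a [cohort_spec()].
#' @param i participant index (1-based); determines the child seeds.
#' @return A list with `recording`, `log`, `truth`, `participant_id`.
#' @export
simulate_participant <- function(spec, i) {
  pid <- sprintf("p%02d", i)
  log <- make_session_log(spec, rng_seed = child_seed(spec$seed, 2L * i),
                          participant_id = pid)
  out <- synthesize_recording(spec, log,
                              rng_seed = child_seed(spec$seed, 2L * i + 1L),
                              participant_id = pid)
  list(recording = out$recording, log = log, truth = out$truth,
       participant_id = pid)
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf("SEEG recording: %d channels x %.1f s at %g Hz (%s)\n",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs,
              x$participant_id %||% "unnamed"))
  tab <- table(x$contacts$tissue)
  cat(sprintf("  contacts: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d ERD contact(s), %d spiky contact(s), %d spike(s)\n",
              length(x$erd_contacts), length(x$spiky_contacts),
              sum(lengths(x$spike_times))))
  invisible(x)
}
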