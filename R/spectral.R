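# Per-trial multitaper PSD estimation, outlier rejection, bootstrap
# confidence intervals, and sliding-window spectrograms.

#' Multitaper power spectral density per trial
#'
#' Computes Slepian-taper spectra (5 tapers, time-bandwidth product 3 by
#' default) for every trial of a windowed epoch matrix, combined with
#' Thomson's adaptive weighting.  The FFT length is the smallest power of two
#' giving a frequency-bin width of at most 0.3 Hz (8192 at 2000 Hz), so
#' spectra live on a finely zero-padded grid.
#'
#' @param epochs trials x samples matrix (one channel, one phase), or a
#'   `phase_epochs` object together with `phase` and `contact_id`.
#' @param fs sampling rate in Hz (taken from `epochs` if it is a
#'   `phase_epochs`).
#' @param n_tapers,nw taper count and time-bandwidth product; `n_tapers`
#'   must not exceed `2 * nw - 1`.
#' @param nfft FFT length; default obeys the 0.3 Hz bin-width bound.
#' @param weighting `"adaptive"` (default) or `"uniform"` taper combination.
#' @param fmax drop bins above this frequency (Hz) to bound memory; `NULL`
#'   keeps the full grid up to Nyquist.
#' @param phase,contact_id selectors when `epochs` is a `phase_epochs`.
#' @return A `psd_estimate`: list with `freqs` (Hz), `power` (trials x bins,
#'   microvolt^2/Hz), `trials`, `fs`, `channel_id`, `phase`.
#' @export
compute_psd <- function(epochs, fs = NULL, n_tapers = 5, nw = 3,
                        nfft = NULL, weighting = c("adaptive", "uniform"),
                        fmax = NULL, phase = NULL, contact_id = NULL) {
  weighting <- match.arg(weighting)
  trials <- NULL
  if (inherits(epochs, "phase_epochs")) {
    if (is.null(phase) || is.null(contact_id)) {
      stopf("phase and contact_id are required with phase_epochs input")
    }
    fs <- epochs$fs
    trials <- epochs$phases[[phase]]$trials
    epochs <- channel_epochs(epochs, phase, contact_id)
  }
  if (is.null(fs)) stopf("fs must be supplied for matrix input")
  x <- as.matrix(epochs)
  if (n_tapers > 2 * nw - 1) {
    stopf("invalid parameter: n_tapers must be <= 2 * nw - 1")
  }
  mt <- mt_psd_matrix(x, fs, nw = nw, k = n_tapers, nfft = nfft,
                      weighting = weighting, fmax = fmax)
  structure(list(freqs = mt$freqs, power = mt$power,
                 trials = trials %||% seq_len(nrow(x)),
                 fs = fs, nfft = mt$nfft, n_tapers = n_tapers, nw = nw,
                 channel_id = contact_id, phase = phase),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("Multitaper PSD: %d trial(s) x %d bins (%.3f Hz/bin, up to %.1f Hz)\n",
              nrow(x$power), length(x$freqs), x$fs / x$nfft,
              max(x$freqs)))
  invisible(x)
}

beta_bins <- function(freqs, band = c(13, 30)) {
  which(freqs >= band[1] & freqs <= band[2])
}

#' Per-trial and channel-level beta-band power statistics
#'
#' The per-trial statistic is the median over in-band bins (robust, used for
#' outlier screening and violin displays); the channel-level statistic is
#' the mean in-band power of the trial-averaged spectrum.
#'
#' @param psd a `psd_estimate`.
#' @param band frequency band in Hz.
#' @return List with `per_trial` (median in-band power per trial),
#'   `channel_mean` (mean in-band power of the trial average), `band`.
#' @export
band_summary <- function(psd, band = c(13, 30)) {
  bins <- beta_bins(psd$freqs, band)
  if (length(bins) == 0) stopf("no frequency bins inside the requested band")
  p <- psd$power[, bins, drop = FALSE]
  list(per_trial = apply(p, 1, stats::median),
       channel_mean = mean(colMeans(p)),
       band = band)
}

upper_fence <- function(v, k = 1.5) {
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  q[2] + k * (q[2] - q[1])
}

#' Two-stage interquartile-range outlier rejection
#'
#' Applied per channel and phase, in order on the surviving set:
#' (a) trials whose time-domain RMS exceeds `Q3 + 1.5 * IQR` of the trial RMS
#' distribution are removed; (b) trials containing a detected interictal
#' spike are removed; (c) trials whose in-band per-trial PSD statistic
#' (median over beta bins) exceeds its own `Q3 + 1.5 * IQR` fence are
#' removed.  With fewer than 4 trials no rejection is attempted.
#'
#' @param epochs trials x samples matrix for the channel/phase.
#' @param psd the matching `psd_estimate` (same trial order).
#' @param spike_trials indices (row positions) of trials overlapping a
#'   detected spike.
#' @param band beta band in Hz.
#' @return List with `kept` (row indices into the input), `removed` (data
#'   frame of `trial` row index and `reason`).
#' @export
reject_outlier_trials <- function(epochs, psd, spike_trials = integer(0),
                                  band = c(13, 30)) {
  x <- as.matrix(epochs)
  n <- nrow(x)
  if (n != nrow(psd$power)) stopf("epochs and psd disagree on trial count")
  if (n < 4) {
    warnf("fewer than 4 trials; outlier rejection skipped")
    return(list(kept = seq_len(n),
                removed = data.frame(trial = integer(0), reason = character(0))))
  }
  removed <- data.frame(trial = integer(0), reason = character(0))
  surviving <- seq_len(n)
  # (a) time-domain RMS fence
  rms <- sqrt(rowMeans(x^2))
  bad <- surviving[rms[surviving] > upper_fence(rms[surviving])]
  if (length(bad)) {
    removed <- rbind(removed, data.frame(trial = bad, reason = "rms"))
    surviving <- setdiff(surviving, bad)
  }
  # (b) interictal spikes inside the window
  bad <- intersect(surviving, spike_trials)
  if (length(bad)) {
    removed <- rbind(removed, data.frame(trial = bad, reason = "spike"))
    surviving <- setdiff(surviving, bad)
  }
  # (c) in-band PSD fence on the survivors
  if (length(surviving) >= 4) {
    bs <- band_summary(psd, band)$per_trial
    bad <- surviving[bs[surviving] > upper_fence(bs[surviving])]
    if (length(bad)) {
      removed <- rbind(removed, data.frame(trial = bad, reason = "psd"))
      surviving <- setdiff(surviving, bad)
    }
  }
  list(kept = surviving, removed = removed)
}

#' Bootstrap confidence interval for the trial-mean spectrum
#'
#' Resamples trials with replacement (`n` draws, default 10000), recomputes
#' the per-bin mean, and reports percentile bounds.
#'
#' @param psd a `psd_estimate`.
#' @param n number of bootstrap resamples.
#' @param seed integer seed.
#' @param level confidence level.
#' @return A `bootstrap_ci`: list with `freqs`, `mean`, `lower`, `upper`,
#'   `n_resamples`, `seed`.
#' @export
bootstrap_ci <- function(psd, n = 10000, seed = 1L, level = 0.95) {
  x <- psd$power
  nt <- nrow(x)
  m <- colMeans(x)
  if (nt < 2) {
    warnf("only one trial: degenerate zero-width interval")
    return(structure(list(freqs = psd$freqs, mean = m, lower = m, upper = m,
                          n_resamples = n, seed = seed),
                     class = "bootstrap_ci"))
  }
  alpha <- (1 - level) / 2
  with_seed(seed, {
    idx <- matrix(sample.int(nt, n * nt, replace = TRUE), n, nt)
    # resample-count matrix: W[i, j] = multiplicity of trial j in resample i,
    # built in one tabulate() pass over linearized (resample, trial) indices
    li <- as.vector(t(idx)) + rep(seq_len(n) - 1L, each = nt) * nt
    W <- matrix(tabulate(li, nbins = n * nt), n, nt, byrow = TRUE)
    means <- (W %*% x) / nt
    qs <- apply(means, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    structure(list(freqs = psd$freqs, mean = m,
                   lower = qs[1, ], upper = qs[2, ],
                   n_resamples = n, seed = seed),
              class = "bootstrap_ci")
  })
}

#' Sliding-window multitaper spectrogram
#'
#' Multitaper spectra (same taper settings as [compute_psd()]) over a 0.3 s
#' window advanced in steps of `(1 - overlap) * window` (0.03 s at the
#' defaults), covering 1--100 Hz; each frequency bin is then z-scored over
#' the segment duration, so sustained band-power drops show as negative
#' z-values.
#'
#' @param x numeric vector (one channel segment) or trials x samples matrix
#'   (trial-averaged power is z-scored).
#' @param fs sampling rate in Hz.
#' @param window_s,overlap sliding-window length (s) and fractional overlap.
#' @param fmin,fmax displayed frequency range in Hz.
#' @param n_tapers,nw taper settings.
#' @param nfft FFT length; default obeys the 0.3 Hz bin-width bound.
#' @return A `spectrogram`: list with `times` (window centers, s), `freqs`
#'   (Hz), `z` (time x freq z-scored power), `power` (raw time x freq).
#' @export
compute_spectrogram <- function(x, fs, window_s = 0.3, overlap = 0.9,
                                fmin = 1, fmax = 100, n_tapers = 5, nw = 3,
                                nfft = NULL) {
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  n <- ncol(xm)
  wlen <- as.integer(round(window_s * fs))
  if (n < wlen) stopf("segment shorter than the spectrogram window")
  step <- max(1L, as.integer(round((1 - overlap) * wlen)))
  starts <- seq(1L, n - wlen + 1L, by = step)
  nfft <- nfft %||% choose_nfft(wlen, fs)
  pw <- NULL
  for (tr in seq_len(nrow(xm))) {
    frames <- t(vapply(starts, function(s0) xm[tr, s0:(s0 + wlen - 1L)],
                       numeric(wlen)))
    mt <- mt_psd_matrix(frames, fs, nw = nw, k = n_tapers, nfft = nfft,
                        weighting = "adaptive", fmax = fmax)
    pw <- if (is.null(pw)) mt$power else pw + mt$power
    freqs <- mt$freqs
  }
  pw <- pw / nrow(xm)
  sel <- freqs >= fmin & freqs <= fmax
  pw <- pw[, sel, drop = FALSE]
  freqs <- freqs[sel]
  mu <- colMeans(pw)
  sd <- apply(pw, 2, stats::sd)
  z <- sweep(sweep(pw, 2, mu), 2, pmax(sd, .Machine$double.xmin), "/")
  structure(list(times = (starts - 1 + wlen / 2) / fs, freqs = freqs,
                 z = z, power = pw),
            class = "spectrogram")
}
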