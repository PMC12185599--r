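# Line-noise removal, spike detection, RMS weights, shaft re-referencing.

fs <- 2000

test_that("compute_rms matches closed forms", {
  expect_equal(compute_rms(rep(3, 100)), 3)
  t <- seq(0, 1 - 1/fs, by = 1/fs)
  expect_equal(compute_rms(5 * sin(2 * pi * 10 * t)), 5 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(compute_rms(c(3, -4)), sqrt(12.5))
  m <- cbind(a = rep(2, 10), b = rep(-2, 10))
  expect_equal(unname(compute_rms(m)), c(2, 2))
  expect_error(compute_rms(numeric(0)), "empty")
})

test_that("weights reproduce the printed formulas exactly", {
  expect_equal(unname(compute_weights(c(2, 2, 2, 2))$weights),
               rep(0.25, 4), tolerance = 1e-12)
  expect_equal(unname(compute_weights(c(1, 3))$weights),
               c(0.625, 0.375), tolerance = 1e-12)
  expect_equal(unname(compute_weights(c(1, 2, 3))$weights),
               c(5/12, 1/3, 1/4), tolerance = 1e-12)
})

test_that("weights are normalized, monotone in RMS, and zero when excluded", {
  set.seed(5)
  for (i in 1:25) {
    r <- runif(sample(2:10, 1), 0.1, 50)
    names(r) <- paste0("c", seq_along(r))
    w <- compute_weights(r)$weights
    expect_equal(sum(w), 1, tolerance = 1e-12)
    ord <- order(r)
    expect_true(all(diff(w[ord]) <= 1e-12))          # larger RMS, smaller weight
    if (length(unique(r)) == length(r)) {
      expect_true(all(diff(w[ord]) < 0))
    }
  }
  w <- compute_weights(c(a = 1, b = 2, c = 3), included = c("a", "c"))
  expect_equal(unname(w$weights["b"]), 0)
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  expect_error(compute_weights(c(a = 1), included = character(0)),
               "no-reference-channels")
  expect_error(compute_weights(c(a = 0, b = 1)), "positive")
})

test_that("weighted re-referencing cancels common structure", {
  set.seed(7)
  n <- 4000
  common <- rnorm(n)
  seg <- cbind(a = common, b = common, c = common)
  w <- compute_weights(compute_rms(seg))
  out <- rereference_weighted(seg, w)
  expect_lt(max(abs(out)), 1e-10)

  # equal-RMS case equals an independently coded mean reference
  x <- matrix(rnorm(n * 4), n, 4)
  x <- sweep(x, 2, apply(x, 2, sd), "/")   # equalize RMS (mean ~ 0)
  x <- sweep(x, 2, colMeans(x))
  colnames(x) <- paste0("c", 1:4)
  wx <- compute_weights(compute_rms(x))
  expect_lt(max(abs(rereference_weighted(x, wx) - oracle_mean_reference(x))),
            1e-10)

  # a channel-constant offset is removed exactly because weights sum to 1
  seg2 <- matrix(rnorm(n * 3), n, 3) + 40
  colnames(seg2) <- paste0("c", 1:3)
  w2 <- compute_weights(compute_rms(seg2))
  expect_equal(rereference_weighted(seg2 + 7, w2),
               rereference_weighted(seg2, w2), tolerance = 1e-12)

  expect_error(rereference_weighted(seg[, 1:2], w), "shaft mismatch")
})

test_that("shared shaft component is suppressed on a heterogeneous shaft", {
  set.seed(8)
  n <- 60 * fs
  t <- (seq_len(n) - 1) / fs
  shared <- 10 * sqrt(2) * sin(2 * pi * 7 * t)
  amp <- c(40, 30, 10, 5)                 # gray vs white heterogeneity
  seg <- vapply(amp, function(a) a / 40 * rnorm(n, sd = 12) + shared,
                numeric(n))
  colnames(seg) <- paste0("c", 1:4)
  w <- compute_weights(compute_rms(seg))
  out <- rereference_weighted(seg, w)
  p_at <- function(v) {
    ps <- Mod(fft(v))^2
    f <- (seq_along(v) - 1) * fs / length(v)
    sum(ps[f >= 6 & f <= 8])
  }
  for (j in 1:4) {
    expect_lt(p_at(out[, j]) / p_at(shared), 0.05)
  }
})

test_that("spike detector finds injected transients and ignores ripple", {
  # flat signal
  ev0 <- detect_spikes(matrix(0, fs, 1), fs = fs)
  expect_equal(nrow(ev0[[1]]), 0)
  # one biphasic 100 uV transient
  x <- numeric(10 * fs)
  w <- seegerd:::spike_waveform(fs, 100, 0.005, 0.08)
  c0 <- 5 * fs; h <- (length(w) - 1) %/% 2
  x[(c0 - h):(c0 + h)] <- w
  ev <- detect_spikes(matrix(x), fs = fs)[[1]]
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$peak_s - (c0 - 1) / fs), 0.010)
  expect_gt(ev$peak_amplitude_uv, 30)
  # sub-threshold broadband ripple: 20 uV peak after the 30 Hz high-pass
  set.seed(9)
  bf <- signal::butter(4, 30 / (fs / 2), type = "high")
  r <- rnorm(10 * fs)
  r <- r / max(abs(signal::filtfilt(bf, r))) * 20
  expect_equal(nrow(detect_spikes(matrix(r), fs = fs)[[1]]), 0)
  # two transients with < 100 ms between their excursions merge into one event
  x2 <- numeric(4 * fs)
  x2[(fs - h):(fs + h)] <- w
  x2[(fs - h):(fs + h) + round(0.09 * fs)] <- x2[(fs - h):(fs + h) + round(0.09 * fs)] + w
  expect_equal(nrow(detect_spikes(matrix(x2), fs = fs)[[1]]), 1)
  # and stay separate events when the gap is wide
  x3 <- numeric(4 * fs)
  x3[(fs - h):(fs + h)] <- w
  x3[(fs - h):(fs + h) + fs] <- w
  expect_equal(nrow(detect_spikes(matrix(x3), fs = fs)[[1]]), 2)
})

test_that("line-noise removal honors its contract", {
  set.seed(10)
  n <- 40 * fs
  t <- (seq_len(n) - 1) / fs
  base <- seegerd:::colored_noise(n, fs, 20, 2)
  bandpow <- function(v, lo, hi) {
    ps <- Mod(fft(v))^2
    f <- (seq_along(v) - 1) * fs / length(v)
    sum(ps[f >= lo & f <= hi])
  }
  # static line: >= 20 dB attenuation at 60 Hz, beta band within 1 dB
  x <- base + 20 * sin(2 * pi * 60 * t + 0.3) + 5 * sin(2 * pi * 120 * t)
  y <- remove_line_noise(matrix(x), fs = fs, n_harmonics = 2)[, 1]
  expect_gt(10 * log10(bandpow(x, 59, 61) / bandpow(y, 59, 61)), 20)
  expect_gt(10 * log10(bandpow(x, 119, 121) / bandpow(y, 119, 121)), 20)
  expect_lt(abs(10 * log10(bandpow(y, 13, 30) / bandpow(x, 13, 30))), 1)
  # nothing to remove: output ~ input
  y0 <- remove_line_noise(matrix(base), fs = fs, n_harmonics = 3)[, 1]
  expect_lt(sd(y0 - base) / sd(base), 0.01)
  # drifting line: residual below 5% of injected power
  drift <- seegerd:::line_noise(n, fs, 20, 60, 1)
  xd <- base + drift
  yd <- remove_line_noise(matrix(xd), fs = fs, n_harmonics = 1)[, 1]
  expect_lt(bandpow(yd, 59, 61) / bandpow(drift, 59, 61), 0.05)
  # harmonic above Nyquist rejected
  expect_error(remove_line_noise(matrix(x), fs = fs, n_harmonics = 20),
               "Nyquist")
})

test_that("demodulation stays transient-safe near spikes", {
  set.seed(12)
  n <- 20 * fs
  t <- (seq_len(n) - 1) / fs
  base <- seegerd:::colored_noise(n, fs, 20, 2)
  w <- seegerd:::spike_waveform(fs, 120, 0.005, 0.08)
  c0 <- 10 * fs; h <- (length(w) - 1) %/% 2
  clean <- base
  clean[(c0 - h):(c0 + h)] <- clean[(c0 - h):(c0 + h)] + w
  x <- clean + 20 * sin(2 * pi * 60 * t)
  y <- remove_line_noise(matrix(x), fs = fs, n_harmonics = 1)[, 1]
  win <- (c0 - fs):(c0 + fs)
  expect_lt(max(abs(y - clean)[win]), 5)   # bounded microvolt deviation
})

test_that("reference comparison ranks weighted ESR at or below ESR", {
  set.seed(13)
  n <- 60 * fs
  # heterogeneous shaft with strong common noise
  shared <- seegerd:::colored_noise(n, fs, 25, 2)
  amp <- c(40, 35, 12, 6)
  sam <- vapply(amp, function(a) rnorm(n, sd = a) + shared, numeric(n))
  contacts <- data.frame(contact_id = paste0("s1_c", 1:4), shaft_id = "s1",
                         index_on_shaft = 0:3, tissue = "gray",
                         hemisphere = "left", laterality = "contralateral")
  colnames(sam) <- contacts$contact_id
  rec <- structure(list(samples = sam, fs = fs, contacts = contacts,
                        participant_id = "fx"), class = "seeg_recording")
  cmp <- compare_references(rec)
  wr <- cmp$mean_abs_r[cmp$method == "weighted_esr"]
  er <- cmp$mean_abs_r[cmp$method == "esr"]
  expect_lte(wr, er)

  # independent equal-amplitude channels: subtracting any sum-to-one
  # reference induces |r| = 1/(C-1) between residuals, and adjacent bipolar
  # derivations share a contact (|r| = 1/2); these closed forms, not zero,
  # are the correct independence baseline
  sam2 <- vapply(1:4, function(i) rnorm(n, sd = 10), numeric(n))
  colnames(sam2) <- contacts$contact_id
  rec2 <- structure(list(samples = sam2, fs = fs, contacts = contacts,
                         participant_id = "fx"), class = "seeg_recording")
  cmp2 <- compare_references(rec2)
  expect_equal(cmp2$mean_abs_r[cmp2$method == "esr"], 1/3, tolerance = 0.05)
  expect_equal(cmp2$mean_abs_r[cmp2$method == "weighted_esr"], 1/3,
               tolerance = 0.05)
  # raw independent channels themselves are uncorrelated
  raw_r <- cor(sam2)
  expect_true(all(abs(raw_r[upper.tri(raw_r)]) < 0.05))

  # bipolar on a 2-contact shaft: single derived channel -> warning, NA
  rec3 <- rec
  rec3$samples <- sam[, 1:2]
  rec3$contacts <- contacts[1:2, ]
  expect_warning(cmp3 <- compare_references(rec3, methods = "bipolar"),
                 "single channel")
  expect_true(is.na(cmp3$mean_abs_r))
})

test_that("epoch re-referencing excludes spiky channels but re-references them", {
  spec <- tiny_spec(n_trials = 6, shaft_common_amp = 30)
  p <- simulate_participant(spec, 1)
  ep <- extract_phase_epochs(p$recording, p$log)
  cid <- p$recording$contacts$contact_id
  ref <- rereference_epochs(ep, exclude = cid[1])
  # excluded channel still changed by the common-signal subtraction
  expect_false(isTRUE(all.equal(channel_epochs(ref, "Delay", cid[1]),
                                channel_epochs(ep, "Delay", cid[1]))))
  # single usable contact -> warning, untouched
  expect_warning(ref2 <- rereference_epochs(ep, exclude = cid[1:3]),
                 "un-re-referenced")
  expect_equal(channel_epochs(ref2, "Delay", cid[4]),
               channel_epochs(ep, "Delay", cid[4]))
})
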