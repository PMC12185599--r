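# Multitaper PSD, outlier rejection, bootstrap CI, spectrogram.

fs <- 2000

test_that("Slepian tapers are orthonormal and well concentrated", {
  dp <- seegerd:::dpss_tapers(256, 3, 5)
  G <- crossprod(dp$tapers)
  expect_equal(G, diag(5), tolerance = 1e-9)
  expect_true(all(dp$eigen > 0.94))
  expect_true(all(diff(dp$eigen) < 0))
  # frozen reference values (independent DPSS implementation, n = 64)
  dp64 <- seegerd:::dpss_tapers(64, 3, 5)
  expect_equal(dp64$eigen,
               c(0.999999873, 0.9999911516, 0.9997233692, 0.9950049123,
                 0.9465841836), tolerance = 1e-7)
  expect_equal(abs(dp64$tapers[c(1, 17, 33), 1]),
               c(0.0003564442, 0.0785507489, 0.2297040105), tolerance = 1e-7)
  expect_equal(abs(dp64$tapers[c(1, 17, 33), 3]),
               c(0.0118392207, 0.1893441482, 0.1533556899), tolerance = 1e-7)
  expect_error(seegerd:::dpss_tapers(256, 3, 6), "invalid parameter")
})

test_that("PSD scaling: zero signal, Parseval, tone location, quadratic amplitude", {
  expect_true(all(compute_psd(matrix(0, 3, 1000), fs = fs)$power == 0))
  set.seed(21)
  x <- matrix(rnorm(20 * 1000), 20)
  psd <- compute_psd(x, fs = fs)
  df <- fs / psd$nfft
  expect_lte(df, 0.3)
  tot <- rowSums(psd$power) * df
  expect_true(all(abs(tot - 1) < 0.15))
  # pure 20 Hz tone: the multitaper response is a flat-topped lobe of
  # half-width nw/T (6 Hz here), so the argmax lies inside the lobe and the
  # lobe's power centroid sits on the tone frequency to within a bin
  t <- (0:999) / fs
  tone <- matrix(10 * sin(2 * pi * 20 * t), 1)
  pt <- compute_psd(tone, fs = fs, fmax = 100)
  W <- 3 / 0.5
  expect_lt(abs(pt$freqs[which.max(pt$power[1, ])] - 20), W + 1e-12)
  centroid <- sum(pt$freqs * pt$power[1, ]) / sum(pt$power[1, ])
  expect_lt(abs(centroid - 20), 2 * df)
  # out-of-lobe leakage is strongly suppressed
  out_lobe <- pt$freqs < 20 - 1.5 * W | pt$freqs > 20 + 1.5 * W
  expect_lt(max(pt$power[1, out_lobe]), max(pt$power[1, ]) / 100)
  # doubling amplitude quadruples in-band power
  p1 <- compute_psd(x, fs = fs, fmax = 35)
  p2 <- compute_psd(2 * x, fs = fs, fmax = 35)
  expect_equal(band_summary(p2)$channel_mean,
               4 * band_summary(p1)$channel_mean, tolerance = 1e-10)
  expect_error(compute_psd(x, fs = fs, n_tapers = 7, nw = 3),
               "invalid parameter")
})

test_that("outlier rejection applies the fences in order", {
  set.seed(22)
  base <- matrix(rnorm(9 * 1000, sd = 10), 9)
  psd <- compute_psd(base, fs = fs, fmax = 35)
  # identical trials: nothing exceeds the fence
  same <- matrix(rep(base[1, ], 8), 8, byrow = TRUE)
  psd_same <- compute_psd(same, fs = fs, fmax = 35)
  r0 <- reject_outlier_trials(same, psd_same)
  expect_equal(r0$kept, 1:8)
  # one trial with 10x RMS is removed by rule (a)
  infl <- base
  infl[5, ] <- infl[5, ] * 10
  r1 <- reject_outlier_trials(infl, compute_psd(infl, fs = fs, fmax = 35))
  expect_true(5 %in% r1$removed$trial)
  expect_equal(r1$removed$reason[r1$removed$trial == 5], "rms")
  # spike-flagged trial removed by rule (b)
  r2 <- reject_outlier_trials(base, psd, spike_trials = 3)
  expect_true(3 %in% r2$removed$trial)
  expect_equal(r2$removed$reason[r2$removed$trial == 3], "spike")
  # beta-inflated trial (same RMS) removed by rule (c)
  t <- (0:999) / fs
  beta_only <- base
  beta_only[7, ] <- c(scale(base[7, ] + 40 * sin(2 * pi * 21 * t))) * 10
  r3 <- reject_outlier_trials(beta_only,
                              compute_psd(beta_only, fs = fs, fmax = 35))
  expect_true(7 %in% r3$removed$trial)
  expect_equal(r3$removed$reason[r3$removed$trial == 7], "psd")
  # fewer than 4 trials: warning, nothing removed
  expect_warning(r4 <- reject_outlier_trials(base[1:3, ],
    compute_psd(base[1:3, ], fs = fs, fmax = 35)), "fewer than 4")
  expect_equal(r4$kept, 1:3)
})

test_that("outlier rejection is conservative on clean Gaussian trials", {
  set.seed(23)
  frac <- replicate(20, {
    x <- matrix(rnorm(30 * 400, sd = 10), 30)
    psd <- compute_psd(x, fs = fs, fmax = 35)
    1 - length(reject_outlier_trials(x, psd)$kept) / 30
  })
  expect_lte(mean(frac), 0.10)
})

test_that("bootstrap CI is seeded, degenerate on constants, and brackets the mean", {
  set.seed(24)
  x <- matrix(rnorm(30 * 5, mean = 50), 30)
  psd <- structure(list(freqs = 1:5, power = x), class = "psd_estimate")
  ci1 <- bootstrap_ci(psd, n = 500, seed = 42)
  ci2 <- bootstrap_ci(psd, n = 500, seed = 42)
  expect_identical(ci1$lower, ci2$lower)
  expect_true(all(ci1$lower <= colMeans(x) & colMeans(x) <= ci1$upper))
  cst <- structure(list(freqs = 1:2, power = matrix(3, 10, 2)),
                   class = "psd_estimate")
  ci3 <- bootstrap_ci(cst, n = 200, seed = 1)
  expect_equal(ci3$lower, ci3$upper)
  one <- structure(list(freqs = 1, power = matrix(2, 1, 1)),
                   class = "psd_estimate")
  expect_warning(ci4 <- bootstrap_ci(one, n = 10, seed = 1), "one trial")
  expect_equal(ci4$lower, ci4$upper)
})

test_that("spectrogram normalizes per frequency and caps the axis at 100 Hz", {
  set.seed(25)
  x <- rnorm(3 * fs, sd = 10)
  sg <- compute_spectrogram(x, fs = fs, nfft = 1024)
  expect_lte(max(sg$freqs), 100)
  expect_gte(min(sg$freqs), 1)
  expect_true(all(abs(colMeans(sg$z)) < 1e-10))
  expect_error(compute_spectrogram(rnorm(100), fs = fs), "shorter")
})

test_that("spectrogram shows negative beta z when the oscillation stops", {
  set.seed(26)
  t <- (seq_len(4 * fs) - 1) / fs
  x <- rnorm(4 * fs, sd = 2) + 15 * sin(2 * pi * 21 * t) * (t < 2)
  sg <- compute_spectrogram(x, fs = fs, nfft = 2048)
  bbin <- which(sg$freqs >= 19 & sg$freqs <= 23)
  late <- sg$times > 2.5
  expect_lt(mean(sg$z[late, bbin]), -0.5)
})
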