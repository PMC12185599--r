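# Discrete prolate spheroidal (Slepian) tapers and multitaper spectra.
#
# Tapers are computed from the classical symmetric tridiagonal eigenproblem
# (Percival & Walden formulation), which is numerically stable for the
# window lengths used here; concentration eigenvalues come from the
# quadratic form with the band-limiting sinc kernel.  Results are cached per
# (n, nw, k) because the same 0.5 s / 0.3 s windows recur throughout an
# analysis.

.taper_cache <- new.env(parent = emptyenv())

#' Slepian tapers and their concentration eigenvalues
#'
#' @param n window length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers; must satisfy `k <= 2 * nw - 1`.
#' @return List with `tapers` (n x k matrix, columns unit-norm) and `eigen`
#'   (length-k in-band concentration values, all close to 1).
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  if (k > 2 * nw - 1) {
    stopf("invalid parameter: %d tapers requested but at most %g are well concentrated for nw = %g",
          k, 2 * nw - 1, nw)
  }
  if (n < 2 * nw + 1) {
    stopf("window of %d samples is too short for nw = %g", n, nw)
  }
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (t[-1] * (n - t[-1]))/2
  A <- matrix(0, n, n)
  A[cbind(t + 1, t + 1)] <- diag_main
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # Slepian sign convention: even-order tapers have positive mean, odd-order
  # tapers a positive initial slope.
  for (j in seq_len(k)) {
    s <- if (j %% 2 == 1) sum(tapers[, j]) else sum(diff(tapers[, j]) * seq_len(n - 1))
    if (s < 0) tapers[, j] <- -tapers[, j]
  }
  # Concentration lambda_k = v' S v with the sinc band-limiting kernel.
  dt_grid <- outer(t, t, "-")
  S <- sin(2 * pi * w * dt_grid) / (pi * dt_grid)
  S[cbind(t + 1, t + 1)] <- 2 * w
  lambda <- vapply(seq_len(k), function(j) {
    v <- tapers[, j]
    as.numeric(v %*% S %*% v)
  }, numeric(1))
  out <- list(tapers = tapers, eigen = pmin(lambda, 1))
  .taper_cache[[key]] <- out
  out
}

# Multitaper spectra for a trials x samples matrix.  Returns one-sided PSDs
# in uV^2/Hz on the zero-padded grid, combined across tapers either with
# Thomson's adaptive weights or as a plain eigenvalue-weighted average.
mt_psd_matrix <- function(x, fs, nw = 3, k = 5, nfft = NULL,
                          weighting = c("adaptive", "uniform"),
                          fmax = NULL) {
  weighting <- match.arg(weighting)
  x <- as.matrix(x)
  n <- ncol(x)
  n_trials <- nrow(x)
  nfft <- nfft %||% choose_nfft(n, fs)
  dp <- dpss_tapers(n, nw, k)
  n_bins <- nfft %/% 2 + 1
  freqs <- (0:(n_bins - 1)) * fs / nfft
  keep <- if (is.null(fmax)) seq_len(n_bins) else which(freqs <= fmax)
  # eigenspectra: for each taper, FFT all trials at once
  eig <- vector("list", k)
  pad <- matrix(0, nfft, n_trials)
  for (j in seq_len(k)) {
    pad[seq_len(n), ] <- t(x) * dp$tapers[, j]
    X <- stats::mvfft(pad)[seq_len(n_bins), , drop = FALSE]
    P <- (Mod(X)^2) / fs
    P[2:(n_bins - 1), ] <- 2 * P[2:(n_bins - 1), ]
    eig[[j]] <- P[keep, , drop = FALSE]
  }
  lambda <- dp$eigen
  power <- matrix(0, n_trials, length(keep))
  for (tr in seq_len(n_trials)) {
    Sk <- vapply(eig, function(P) P[, tr], numeric(length(keep)))
    if (weighting == "uniform") {
      power[tr, ] <- as.vector(Sk %*% (lambda / sum(lambda)))
    } else {
      power[tr, ] <- adaptive_combine(Sk, lambda, sum(x[tr, ]^2) / n / fs)
    }
  }
  list(freqs = freqs[keep], power = power, nfft = nfft)
}

# Thomson adaptive weighting: iterate S(f) <- sum_k lambda_k d_k^2 S_k /
# sum_k lambda_k d_k^2 with d_k = S / (lambda_k S + (1 - lambda_k) sigma2).
# sigma2 is the process variance expressed as average density (var / fs in
# two-sided terms; the constant only balances the bias term).
adaptive_combine <- function(Sk, lambda, sigma2, iter = 5) {
  if (sigma2 <= 0) return(rowMeans(Sk))
  S <- (Sk[, 1] + Sk[, min(2, ncol(Sk))]) / 2
  for (it in seq_len(iter)) {
    num <- 0
    den <- 0
    for (j in seq_along(lambda)) {
      d2 <- (S / (lambda[j] * S + (1 - lambda[j]) * sigma2))^2 * lambda[j]
      num <- num + d2 * Sk[, j]
      den <- den + d2
    }
    S <- num / pmax(den, .Machine$double.xmin)
  }
  S
}
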