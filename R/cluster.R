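# Frequency-cluster permutation testing of between-phase power contrasts.

#' Wilcoxon signed-rank z-score for paired differences
#'
#' Zero differences are dropped, ranks of the absolute differences are
#' averaged over ties, and the signed-rank statistic `W+` is converted to a
#' z-score via the normal approximation with tie-corrected variance.  The
#' sign convention is positive z when the first condition exceeds the second
#' (differences `a - b` mostly positive).
#'
#' @param d numeric vector of paired differences.
#' @return A single z-score (0, with a warning, when every difference is
#'   zero).
#' @export
wilcoxon_z <- function(d) {
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    warnf("all paired differences are zero; z = 0")
    return(0)
  }
  r <- rank(abs(nz))
  n <- length(nz)
  wplus <- sum(r[nz > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(0)
  (wplus - mu) / sqrt(sigma2)
}

# Signed-rank decomposition for fast permutation: returns a trials x bins
# matrix M with M[i, b] = sign(d[i, b]) * rank_b(|d[i, b]|) / (2 * sd_b),
# so that colSums(M) reproduces the per-bin z-scores and, for a sign vector
# s (label swaps), s %*% M gives the permuted z-scores in one product.
signed_rank_prep <- function(D) {
  n <- nrow(D)
  M <- matrix(0, n, ncol(D))
  for (b in seq_len(ncol(D))) {
    d <- D[, b]
    nz <- which(d != 0)
    if (length(nz) == 0) next
    r <- rank(abs(d[nz]))
    m <- length(nz)
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) next
    M[nz, b] <- sign(d[nz]) * r / (2 * sqrt(sigma2))
  }
  M
}

#' Find supra-threshold frequency clusters
#'
#' Clusters are maximal runs of adjacent qualifying bins sharing a sign,
#' with mass equal to the sum of their z-scores.  One-tailed: bins qualify
#' when `z > threshold` (the hypothesized positive direction).  Two-tailed:
#' bins qualify when `|z| > threshold`, and a sign change breaks a run into
#' separate clusters.
#'
#' @param z per-bin z-scores.
#' @param threshold positive cluster-forming threshold (1.645 one-tailed,
#'   1.96 two-tailed by convention).
#' @param tail `"one"` or `"two"`.
#' @return Data frame with columns `start`, `end` (bin indices) and `mass`.
#' @export
find_clusters <- function(z, threshold, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (threshold <= 0) stopf("threshold must be positive")
  state <- if (tail == "one") as.integer(z > threshold) else
    sign(z) * (abs(z) > threshold)
  empty <- data.frame(start = integer(0), end = integer(0), mass = numeric(0))
  if (!any(state != 0)) return(empty)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  use <- r$values != 0
  data.frame(
    start = starts[use],
    end = ends[use],
    mass = vapply(which(use), function(i) sum(z[starts[i]:ends[i]]),
                  numeric(1))
  )
}

# Max cluster statistic of a z-vector (0 when no cluster forms).
max_cluster_stat <- function(z, threshold, tail) {
  cl <- find_clusters(z, threshold, tail)
  if (nrow(cl) == 0) 0 else max(abs(cl$mass))
}

#' Cluster-based permutation test for a between-phase power contrast
#'
#' For each in-band frequency bin a Wilcoxon signed-rank z is computed
#' between paired trials of two phases; supra-threshold bins are grouped
#' into same-sign clusters; the observed statistic is the maximum absolute
#' cluster mass.  The null is built by randomly swapping the phase labels of
#' each trial pair (independent fair coin per pair) and recomputing the
#' statistic; `p = (1 + #(null >= observed)) / (n_perm + 1)`.  When the test
#' is significant at `alpha`, the reported frequency range is that of the
#' largest cluster.
#'
#' @param psd_a,psd_b `psd_estimate`s (or plain trials x bins matrices with
#'   `freqs` supplied) holding the *same trials in the same order* for the
#'   two phases.
#' @param tail `"one"` tests `a > b`; `"two"` tests `a != b`.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation draws.
#' @param band frequency band tested (Hz).
#' @param threshold cluster-forming z threshold; defaults to 1.645
#'   one-tailed, 1.96 two-tailed.
#' @param alpha significance level for reporting a frequency range.
#' @param freqs frequency grid when matrices are supplied.
#' @return A `cluster_test`: list with per-bin `z`, `freqs`, `clusters`,
#'   `observed_stat`, `null_stats`, `p_value`, `significant`,
#'   `significant_range`, `tail`, `n_perm`, `seed`, `n_pairs`.
#' @export
cluster_permutation_test <- function(psd_a, psd_b, tail = c("one", "two"),
                                     n_perm = 5000, seed = 1L,
                                     band = c(13, 30), threshold = NULL,
                                     alpha = 0.05, freqs = NULL) {
  tail <- match.arg(tail)
  threshold <- threshold %||% if (tail == "one") 1.645 else 1.96
  if (inherits(psd_a, "psd_estimate")) {
    freqs <- psd_a$freqs
    A <- psd_a$power
    B <- psd_b$power
  } else {
    A <- as.matrix(psd_a)
    B <- as.matrix(psd_b)
  }
  if (is.null(freqs)) stopf("a frequency grid is required")
  if (!all(dim(A) == dim(B))) stopf("phase PSDs must be paired trial-for-trial")
  bins <- beta_bins(freqs, band)
  if (length(bins) == 0) stopf("no frequency bins inside the tested band")
  f <- freqs[bins]
  D <- A[, bins, drop = FALSE] - B[, bins, drop = FALSE]
  n <- nrow(D)
  M <- signed_rank_prep(D)
  z <- colSums(M)
  clusters <- find_clusters(z, threshold, tail)
  observed <- if (nrow(clusters) == 0) 0 else max(abs(clusters$mass))
  null_stats <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    Zp <- S %*% M
    vapply(seq_len(n_perm), function(i) {
      max_cluster_stat(Zp[i, ], threshold, tail)
    }, numeric(1))
  })
  p <- if (nrow(clusters) == 0) 1 else
    (1 + sum(null_stats >= observed)) / (n_perm + 1)
  significant <- p < alpha && nrow(clusters) > 0
  sig_range <- NULL
  if (significant) {
    top <- which.max(abs(clusters$mass))
    sig_range <- c(f[clusters$start[top]], f[clusters$end[top]])
  }
  structure(list(z = z, freqs = f, clusters = clusters,
                 observed_stat = observed, null_stats = null_stats,
                 p_value = p, significant = significant,
                 significant_range = sig_range, tail = tail,
                 threshold = threshold, n_perm = n_perm, seed = seed,
                 n_pairs = n),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s-tailed, %d pairs, %d permutations)\n",
              x$tail, x$n_pairs, x$n_perm))
  cat(sprintf("  %d cluster(s), max |mass| = %.2f, p = %.4g\n",
              nrow(x$clusters), x$observed_stat, x$p_value))
  if (!is.null(x$significant_range)) {
    cat(sprintf("  significant range: %.2f-%.2f Hz\n",
                x$significant_range[1], x$significant_range[2]))
  }
  invisible(x)
}
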