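# Internal helpers shared across modules.

#' @importFrom stats fft rnorm runif rexp pnorm qnorm sd
NULL

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed derivation, kept within 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(index)) %% 2147483629)
}

# Centered moving average with shrinking windows at the edges, O(n) via
# cumulative sums.  Works for complex input (used by line-noise demodulation).
moving_average <- function(x, half_width) {
  n <- length(x)
  h <- as.integer(half_width)
  cs <- cumsum(x)
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h, 1L)
  tot <- cs[hi] - cs[lo] + x[lo]
  tot / (hi - lo + 1)
}

# Smallest power of two `nfft` such that fs / nfft <= max_bin_hz.
choose_nfft <- function(n, fs, max_bin_hz = 0.3) {
  nfft <- 2^ceiling(log2(max(n, fs / max_bin_hz)))
  as.integer(nfft)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

task_phases <- function() c("ITI", "Fixation", "Cue", "Delay", "Response")
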