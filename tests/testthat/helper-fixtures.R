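# Shared fixtures, all generated in code.

# A small, fast cohort spec for structural tests.
tiny_spec <- function(...) {
  args <- list(n_participants = 1, shafts_per_participant = 1,
               contacts_per_shaft = 4, n_trials = 8, seed = 101L)
  user <- list(...)
  args[names(user)] <- user
  do.call(cohort_spec, args)
}

# Hand-built session log with explicit phase durations (seconds).  Rows are
# laid out contiguously starting at t = 0.
manual_log <- function(iti, fixation, delay, response, cue = NULL,
                       success = NULL, response_time = NULL,
                       target = NULL) {
  n <- length(response)
  cue <- cue %||% rep(0.25, n)
  iti <- rep_len(iti, n); fixation <- rep_len(fixation, n)
  delay <- rep_len(delay, n)
  durs <- cbind(ITI = iti, Fixation = fixation, Cue = cue,
                Delay = delay, Response = response)
  trial_start <- cumsum(c(0, rowSums(durs)[-n]))
  log <- data.frame(
    trial_id = seq_len(n),
    target_index = target %||% rep(0:7, length.out = n),
    response_time = response_time %||% response,
    success = success %||% rep(TRUE, n)
  )
  onsets <- trial_start + cbind(0, iti, iti + fixation, iti + fixation + cue,
                                iti + fixation + cue + delay)
  phases <- c("ITI", "Fixation", "Cue", "Delay", "Response")
  for (i in seq_along(phases)) {
    log[[paste0(tolower(phases[i]), "_onset")]] <- onsets[, i]
    log[[paste0(tolower(phases[i]), "_duration")]] <- durs[, i]
  }
  attr(log, "participant_id") <- "fixture"
  attr(log, "handedness") <- "right"
  class(log) <- c("session_log", "data.frame")
  log
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# White-noise epoch matrices (trials x samples); condition B carries a
# uniform in-band power drop via amplitude scaling.
white_epochs <- function(n_trials, n_samples, sd = 20, power_scale = 1) {
  matrix(rnorm(n_trials * n_samples, sd = sd * sqrt(power_scale)), n_trials)
}

# Independently coded reference algorithms used as oracles -----------------

# Plain electrode-shaft reference: subtract the unweighted channel mean.
oracle_mean_reference <- function(segment) {
  segment - rowMeans(segment)
}

# Straightforward O(n) cluster enumeration with explicit state tracking,
# independent of the rle-based implementation.  Returns parallel vectors.
oracle_clusters <- function(z, thr, tail) {
  q <- if (tail == "one") z > thr else abs(z) > thr
  starts <- integer(0); ends <- integer(0); masses <- numeric(0)
  open <- FALSE; s0 <- 0L; m <- 0; sg <- 0
  for (i in seq_along(z)) {
    si <- sign(z[i])
    if (q[i] && open && (tail == "one" || si == sg)) {
      m <- m + z[i]
    } else {
      if (open) {
        starts <- c(starts, s0); ends <- c(ends, i - 1L); masses <- c(masses, m)
        open <- FALSE
      }
      if (q[i]) {
        open <- TRUE; s0 <- i; m <- z[i]; sg <- si
      }
    }
  }
  if (open) {
    starts <- c(starts, s0); ends <- c(ends, length(z)); masses <- c(masses, m)
  }
  list(start = starts, end = ends, mass = masses)
}

# Exact signed-rank p-value P(W+ >= w_obs) by full enumeration of the 2^n
# sign patterns (ties in |d| handled by average ranks, zeros dropped).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(w_all >= w_obs)
}
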