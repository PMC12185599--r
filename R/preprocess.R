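# Preprocessing: line-noise removal, interictal spike detection, and
# RMS-weighted electrode shaft re-referencing.

#' Remove power-line noise and its harmonics
#'
#' The default `"demod"` method tracks each harmonic by complex demodulation:
#' the signal is mixed down to DC at the harmonic frequency, the (slowly
#' drifting) complex amplitude is estimated with a centered moving average,
#' and the reconstructed line component is subtracted.  This follows the line
#' component through slow amplitude and phase drift and, being a short
#' linear-phase smoother, does not ring at sharp transients the way an IIR
#' notch does.  A static Butterworth band-stop fallback (`method = "notch"`)
#' is provided for comparison.
#'
#' @param rec a `seeg_recording` (or a plain numeric matrix time x channels
#'   with `fs` supplied).
#' @param f0 fundamental line frequency in Hz.
#' @param n_harmonics number of harmonics to remove (including `f0`).
#' @param track_bw_hz full tracking bandwidth around each harmonic; drift
#'   slower than `track_bw_hz / 2` is followed and removed.
#' @param method `"demod"` (default) or `"notch"`.
#' @param fs sampling rate, only needed for matrix input.
#' @return The input with line components removed (same class).
#' @export
remove_line_noise <- function(rec, f0 = 60, n_harmonics = 3,
                              track_bw_hz = 1, method = c("demod", "notch"),
                              fs = NULL) {
  method <- match.arg(method)
  is_rec <- inherits(rec, "seeg_recording")
  x <- if (is_rec) rec$samples else as.matrix(rec)
  fs <- if (is_rec) rec$fs else fs
  if (is.null(fs)) stopf("fs must be supplied for matrix input")
  if (n_harmonics < 1) return(rec)
  if (f0 * n_harmonics >= fs / 2) {
    stopf("invalid parameter: harmonic %g Hz is at or above Nyquist (%g Hz)",
          f0 * n_harmonics, fs / 2)
  }
  n <- nrow(x)
  if (method == "demod") {
    half <- max(1L, as.integer(round(fs / track_bw_hz / 2)))
    t <- (seq_len(n) - 1) / fs
    for (k in seq_len(n_harmonics)) {
      carrier <- exp(-2i * pi * k * f0 * t)
      for (j in seq_len(ncol(x))) {
        z <- moving_average(x[, j] * carrier, half)
        x[, j] <- x[, j] - 2 * Re(z * Conj(carrier))
      }
    }
  } else {
    for (k in seq_len(n_harmonics)) {
      w <- c(k * f0 - 1, k * f0 + 1) / (fs / 2)
      bf <- signal::butter(2, w, type = "stop")
      for (j in seq_len(ncol(x))) {
        x[, j] <- signal::filtfilt(bf, x[, j])
      }
    }
  }
  if (is_rec) {
    rec$samples <- x
    rec
  } else {
    x
  }
}

#' Detect interictal spikes by fixed thresholding
#'
#' Each channel is high-pass filtered (zero-phase 4th-order Butterworth, 30 Hz
#' by default) and samples whose absolute filtered amplitude exceeds the
#' threshold (30 microvolt) are marked.  Supra-threshold excursions separated
#' by less than `merge_gap_s` are merged into a single event.
#'
#' @param rec a `seeg_recording` or numeric matrix (then supply `fs`).
#' @param hp_cutoff high-pass cutoff in Hz.
#' @param threshold_uv detection threshold in microvolt.
#' @param merge_gap_s excursions closer than this merge into one event.
#' @param fs sampling rate for matrix input.
#' @return A `spike_events` object: a named list (one element per channel) of
#'   data frames with columns `onset_s` (first threshold crossing), `peak_s`
#'   (time of maximum filtered amplitude) and `peak_amplitude_uv`.
#' @export
detect_spikes <- function(rec, hp_cutoff = 30, threshold_uv = 30,
                          merge_gap_s = 0.1, fs = NULL) {
  is_rec <- inherits(rec, "seeg_recording")
  x <- if (is_rec) rec$samples else as.matrix(rec)
  fs <- if (is_rec) rec$fs else fs
  if (is.null(fs)) stopf("fs must be supplied for matrix input")
  if (hp_cutoff >= fs / 2) stopf("invalid parameter: hp_cutoff above Nyquist")
  ids <- if (is_rec) rec$contacts$contact_id else
    (colnames(x) %||% paste0("ch", seq_len(ncol(x))))
  bf <- signal::butter(4, hp_cutoff / (fs / 2), type = "high")
  gap <- as.integer(round(merge_gap_s * fs))
  out <- stats::setNames(vector("list", ncol(x)), ids)
  for (j in seq_len(ncol(x))) {
    y <- signal::filtfilt(bf, x[, j])
    above <- abs(y) > threshold_uv
    out[[j]] <- excursions_to_events(y, above, fs, gap)
  }
  structure(out, class = "spike_events")
}

excursions_to_events <- function(y, above, fs, gap) {
  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      peak_amplitude_uv = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ex <- cbind(start = starts[r$values], end = ends[r$values])
  # merge excursions separated by < gap samples
  merged <- list(ex[1, ])
  if (nrow(ex) > 1) {
    for (i in 2:nrow(ex)) {
      last <- merged[[length(merged)]]
      if (ex[i, "start"] - last["end"] < gap) {
        last["end"] <- ex[i, "end"]
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1]] <- ex[i, ]
      }
    }
  }
  m <- do.call(rbind, merged)
  peak_idx <- vapply(seq_len(nrow(m)), function(i) {
    sel <- m[i, "start"]:m[i, "end"]
    sel[which.max(abs(y[sel]))]
  }, numeric(1))
  data.frame(
    onset_s = (m[, "start"] - 1) / fs,
    peak_s = (peak_idx - 1) / fs,
    peak_amplitude_uv = abs(y[peak_idx])
  )
}

#' Channels carrying at least one detected spike
#'
#' @param spikes a `spike_events` object.
#' @return Character vector of channel ids with one or more events.
#' @export
spiky_channels <- function(spikes) {
  names(spikes)[vapply(spikes, nrow, integer(1)) > 0]
}

#' Root-mean-square amplitude per channel
#'
#' @param segment numeric vector or time x channels matrix, microvolt.
#' @return Per-channel RMS in microvolt.
#' @export
compute_rms <- function(segment) {
  if (length(segment) == 0) stopf("empty segment")
  if (is.matrix(segment)) sqrt(colMeans(segment^2)) else sqrt(mean(segment^2))
}

#' RMS-inverse re-referencing weights for one shaft
#'
#' Contacts with larger RMS amplitude receive strictly smaller weight when
#' forming the shaft's common-noise estimate, so high-amplitude (typically
#' gray matter) contacts cannot dominate the reference.  Over the included
#' contacts the reflected amplitude is `rms_hat_i = -rms_i + 2 * max(rms)`
#' (the `2 * max` term keeps it positive) and the weight is
#' `w_i = rms_hat_i / sum_j rms_hat_j`.  Excluded contacts (e.g. channels
#' carrying interictal spikes) get weight zero but are still re-referenced.
#'
#' @param rms named numeric vector of per-contact RMS values for one shaft.
#' @param included contact names used to build the reference (default: all).
#' @param shaft_id optional shaft label carried in the result.
#' @return A `weight_vector`: list with `weights` (named, sums to 1 over the
#'   shaft), `included`, `shaft_id`.
#' @export
compute_weights <- function(rms, included = names(rms), shaft_id = NULL) {
  if (is.null(names(rms))) names(rms) <- paste0("c", seq_along(rms))
  if (length(included) == 0) {
    stopf("no-reference-channels: the included set is empty")
  }
  if (!all(included %in% names(rms))) {
    stopf("included contacts not present in the RMS vector")
  }
  r <- rms[included]
  if (any(!is.finite(r)) || any(r <= 0)) {
    stopf("invalid input: RMS values must be positive and finite")
  }
  hat <- -r + 2 * max(r)
  w_in <- hat / sum(hat)
  w <- stats::setNames(rep(0, length(rms)), names(rms))
  w[included] <- w_in
  structure(list(weights = w, included = included, shaft_id = shaft_id),
            class = "weight_vector")
}

#' Apply weighted shaft re-referencing to a segment
#'
#' Subtracts the weighted common signal `sum_i w_i s_i` from every channel of
#' the segment, including channels excluded from the weight computation.
#'
#' @param segment time x channels matrix whose columns are the shaft's
#'   contacts (named as in `weights`).
#' @param weights a `weight_vector` from [compute_weights()].
#' @return The re-referenced segment.
#' @export
rereference_weighted <- function(segment, weights) {
  segment <- as.matrix(segment)
  w <- weights$weights
  if (!is.null(colnames(segment))) {
    if (!setequal(colnames(segment), names(w))) {
      stopf("shaft mismatch: segment channels do not match the weight vector")
    }
    w <- w[colnames(segment)]
  } else if (ncol(segment) != length(w)) {
    stopf("shaft mismatch: segment has %d channels but weights have %d",
          ncol(segment), length(w))
  }
  common <- as.vector(segment %*% w)
  segment - common
}

#' Re-reference phase epochs shaft by shaft
#'
#' For every phase and trial, each shaft's segment is re-referenced with
#' RMS-inverse weights.  Channels listed in `exclude` (typically those with
#' detected interictal spikes) contribute zero weight to the reference but
#' are themselves re-referenced.  Shafts with a single contact, or with all
#' contacts excluded, are left untouched with a warning: for them the weight
#' formulas degenerate (a single included contact would subtract itself).
#'
#' @param epochs a `phase_epochs` object.
#' @param exclude contact ids excluded from the weight computation.
#' @param rms_scope `"segment"` (weights recomputed from each phase-by-trial
#'   segment, the default) or `"global"` (one weight vector per shaft from
#'   the RMS over all segments).
#' @return The re-referenced `phase_epochs`.
#' @export
rereference_epochs <- function(epochs, exclude = character(0),
                               rms_scope = c("segment", "global")) {
  rms_scope <- match.arg(rms_scope)
  contacts <- epochs$contacts
  shafts <- split(seq_len(nrow(contacts)), contacts$shaft_id)
  warned <- character(0)
  global_w <- list()
  if (rms_scope == "global") {
    for (sid in names(shafts)) {
      cols <- shafts[[sid]]
      ids <- contacts$contact_id[cols]
      inc <- setdiff(ids, exclude)
      if (length(cols) < 2 || length(inc) < 2) next
      sq <- stats::setNames(numeric(length(cols)), ids)
      nsamp <- 0
      for (ph in names(epochs$phases)) {
        d <- epochs$phases[[ph]]$data[, , cols, drop = FALSE]
        sq <- sq + apply(d^2, 3, sum)
        nsamp <- nsamp + dim(d)[1] * dim(d)[2]
      }
      global_w[[sid]] <- compute_weights(sqrt(sq / nsamp), inc, sid)
    }
  }
  for (sid in names(shafts)) {
    cols <- shafts[[sid]]
    ids <- contacts$contact_id[cols]
    inc <- setdiff(ids, exclude)
    if (length(cols) < 2 || length(inc) < 2) {
      if (!sid %in% warned) {
        warnf("shaft %s left un-re-referenced (fewer than two usable contacts)", sid)
        warned <- c(warned, sid)
      }
      next
    }
    for (ph in names(epochs$phases)) {
      arr <- epochs$phases[[ph]]$data
      for (tr in seq_len(dim(arr)[1])) {
        seg <- arr[tr, , cols, drop = FALSE]
        dim(seg) <- dim(seg)[2:3]
        colnames(seg) <- ids
        w <- if (rms_scope == "global") global_w[[sid]] else
          compute_weights(compute_rms(seg), inc, sid)
        arr[tr, , cols] <- rereference_weighted(seg, w)
      }
      epochs$phases[[ph]]$data <- arr
    }
  }
  epochs
}

#' Compare re-referencing schemes by residual within-shaft correlation
#'
#' Applies weighted shaft re-referencing, standard shaft re-referencing
#' (mean subtraction) and bipolar derivation to a recording and reports, per
#' method, the mean absolute pairwise Pearson correlation over all
#' within-shaft channel pairs.  Lower values mean the shared component was
#' removed more cleanly.
#'
#' @param rec a `seeg_recording`.
#' @param methods subset of `c("weighted_esr", "esr", "bipolar")`.
#' @param include optional contact ids used for the weighted reference
#'   (default: all).
#' @return A data frame with columns `method`, `mean_abs_r`, `n_pairs`.
#' @export
compare_references <- function(rec,
                               methods = c("weighted_esr", "esr", "bipolar"),
                               include = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  contacts <- rec$contacts
  shafts <- split(seq_len(nrow(contacts)), contacts$shaft_id)
  res <- lapply(methods, function(m) c(sum_r = 0, n = 0))
  names(res) <- methods
  for (sid in names(shafts)) {
    cols <- shafts[[sid]]
    if (length(cols) < 2) {
      warnf("shaft %s skipped: fewer than two contacts", sid)
      next
    }
    seg <- rec$samples[, cols, drop = FALSE]
    colnames(seg) <- contacts$contact_id[cols]
    for (m in methods) {
      ref <- switch(m,
        weighted_esr = {
          inc <- if (is.null(include)) colnames(seg) else
            intersect(include, colnames(seg))
          rereference_weighted(seg, compute_weights(compute_rms(seg), inc, sid))
        },
        esr = seg - rowMeans(seg),
        bipolar = seg[, -1, drop = FALSE] - seg[, -ncol(seg), drop = FALSE]
      )
      if (ncol(ref) < 2) {
        warnf("method %s on shaft %s yields a single channel; correlation undefined",
              m, sid)
        next
      }
      r <- stats::cor(ref)
      off <- abs(r[upper.tri(r)])
      res[[m]]["sum_r"] <- res[[m]]["sum_r"] + sum(off)
      res[[m]]["n"] <- res[[m]]["n"] + length(off)
    }
  }
  data.frame(
    method = methods,
    mean_abs_r = vapply(methods, function(m) {
      if (res[[m]]["n"] == 0) NA_real_ else res[[m]]["sum_r"] / res[[m]]["n"]
    }, numeric(1)),
    n_pairs = vapply(methods, function(m) unname(res[[m]]["n"]), numeric(1)),
    row.names = NULL
  )
}
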