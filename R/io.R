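# Standard-format I/O: EDF recordings, events and contact-metadata TSV,
# ground-truth JSON.  The EDF codec implements the continuous 16-bit layout
# (ASCII header blocks followed by little-endian integer data records).

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)
}

num_field <- function(x, width) pad_field(format(x, scientific = FALSE, trim = TRUE), width)

# Render a number so that it fits an 8-character EDF header field and can be
# parsed back exactly; the parsed value is what scaling must use.
edf_num8 <- function(x) {
  # at most 7 characters so the negated value also fits in 8
  for (d in 7:1) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= 7) return(s)
  }
  substr(sprintf("%g", x), 1, 7)
}

#' Write a recording to an EDF file
#'
#' Signals are stored as 16-bit integers with per-channel symmetric physical
#' scaling in microvolt and a one-second record duration.  The final record
#' is zero-padded when the signal length is not a whole number of records.
#'
#' @param rec a `seeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  x <- rec$samples
  fs <- rec$fs
  ns <- ncol(x)
  spr <- as.integer(fs)          # samples per 1 s record
  n_rec <- as.integer(ceiling(nrow(x) / spr))
  amax_str <- vapply(pmax(apply(abs(x), 2, max), 1e-6), edf_num8, character(1))
  amax <- as.numeric(amax_str)   # scale from the value actually written
  labels <- rec$contacts$contact_id
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$participant_id %||% "X", 80),
    pad_field("synthetic SEEG", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    num_field(256 * (1 + ns), 8),
    pad_field("", 44),
    num_field(n_rec, 8),
    num_field(1, 8),
    num_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(vapply(labels, pad_field, character(1), width = 16), collapse = ""),
    paste(rep(pad_field("SEEG", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(paste0("-", amax_str), pad_field, character(1), width = 8), collapse = ""),
    paste(vapply(amax_str, pad_field, character(1), width = 8), collapse = ""),
    paste(rep(num_field(-32768, 8), ns), collapse = ""),
    paste(rep(num_field(32767, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(num_field(spr, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(sig_hdr, con, eos = NULL)
  # standard EDF scaling: value = physmin + (d - digmin) * scale
  scale <- 2 * amax / 65535
  for (r in seq_len(n_rec)) {
    i0 <- (r - 1L) * spr + 1L
    for (j in seq_len(ns)) {
      seg <- numeric(spr)
      avail <- min(nrow(x) - i0 + 1L, spr)
      if (avail > 0) seg[seq_len(avail)] <- x[i0:(i0 + avail - 1L), j]
      d <- round((seg + amax[j]) / scale[j]) - 32768
      d <- as.integer(pmin(pmax(d, -32768), 32767))
      writeBin(d, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param contacts optional contact metadata to attach; when omitted a
#'   minimal table is reconstructed from the channel labels.
#' @return A `seeg_recording` (length a whole number of records; any
#'   zero-padding from writing is retained).
#' @export
read_edf <- function(path, contacts = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchar) readChar(con, nchar, useBytes = TRUE)
  rd(8)
  patient <- trimws(rd(80))
  rd(80 + 8 + 8)
  rd(8)                         # header bytes
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  rd(80 * ns + 8 * ns)
  physmin <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), character(1))))
  physmax <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), character(1))))
  digmin <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), character(1))))
  digmax <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), character(1))))
  rd(80 * ns)
  spr <- as.integer(trimws(vapply(seq_len(ns), function(i) rd(8), character(1))))
  rd(32 * ns)
  fs <- spr[1] / rec_dur
  x <- matrix(0, n_rec * spr[1], ns)
  scale <- (physmax - physmin) / (digmax - digmin)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[j], size = 2, endian = "little")
      x[((r - 1L) * spr[j] + 1L):(r * spr[j]), j] <-
        physmin[j] + (d - digmin[j]) * scale[j]
    }
  }
  colnames(x) <- labels
  if (is.null(contacts)) {
    contacts <- data.frame(contact_id = labels,
                           shaft_id = sub("_c[0-9]+$", "", labels),
                           index_on_shaft = seq_along(labels) - 1L,
                           tissue = "gray", hemisphere = "left",
                           laterality = "contralateral",
                           stringsAsFactors = FALSE)
  }
  structure(list(samples = x, fs = fs, contacts = contacts,
                 participant_id = patient),
            class = "seeg_recording")
}

#' Write / read the events table
#'
#' The events dialect is a long TSV with one row per trial and phase:
#' columns `trial`, `phase`, `onset_s`, `duration_s`, `target_index`,
#' `response_time`, `success`.
#'
#' @param log a `session_log`.
#' @param path TSV path.
#' @return `path` invisibly (writer); a `session_log` (reader).
#' @export
write_events_tsv <- function(log, path) {
  rows <- do.call(rbind, lapply(task_phases(), function(ph) {
    iv <- phase_intervals(log, ph)
    data.frame(trial = iv$trial_id, phase = ph, onset_s = iv$onset,
               duration_s = iv$duration,
               target_index = log$target_index,
               response_time = log$response_time,
               success = log$success, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$trial, rows$onset_s), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param participant_id identifier attached to the log on read.
#' @export
read_events_tsv <- function(path, participant_id = "p01") {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  trials <- sort(unique(ev$trial))
  log <- data.frame(trial_id = trials)
  first <- ev[match(trials, ev$trial), ]
  log$target_index <- first$target_index
  log$response_time <- first$response_time
  log$success <- as.logical(first$success)
  for (ph in task_phases()) {
    sel <- ev[ev$phase == ph, ]
    sel <- sel[match(trials, sel$trial), ]
    log[[paste0(tolower(ph), "_onset")]] <- sel$onset_s
    log[[paste0(tolower(ph), "_duration")]] <- sel$duration_s
  }
  attr(log, "participant_id") <- participant_id
  attr(log, "handedness") <- "right"
  class(log) <- c("session_log", "data.frame")
  log
}

#' Write / read contact metadata TSV
#'
#' @param contacts contact metadata data frame.
#' @param path TSV path.
#' @export
write_contacts_tsv <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contacts_tsv
#' @export
read_contacts_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read ground truth JSON
#'
#' @param truth a `ground_truth`.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$erd_contacts <- as.character(x$erd_contacts)
  x$spiky_contacts <- as.character(x$spiky_contacts)
  x$spike_times <- lapply(x$spike_times, as.numeric)
  structure(x, class = "ground_truth")
}

#' Simulate a cohort and write it to disk
#'
#' One EDF + events TSV + contacts TSV + ground-truth JSON set per
#' participant.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @return Data frame manifest with one row per participant.
#' @export
simulate_to_dir <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(spec$n_participants), function(i) {
    p <- simulate_participant(spec, i)
    pid <- p$participant_id
    edf <- file.path(dir, paste0(pid, ".edf"))
    write_edf(p$recording, edf)
    ev <- file.path(dir, paste0(pid, "_events.tsv"))
    write_events_tsv(p$log, ev)
    ct <- file.path(dir, paste0(pid, "_contacts.tsv"))
    write_contacts_tsv(p$recording$contacts, ct)
    tj <- file.path(dir, paste0(pid, "_truth.json"))
    write_truth_json(p$truth, tj)
    data.frame(participant_id = pid, edf = edf, events = ev,
               contacts = ct, truth = tj, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
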