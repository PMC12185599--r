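# Cohort-level modulation summaries and the laterality proportion test.

#' Summarize per-contact modulation into participant x hemisphere rows
#'
#' For one contrast, takes the per-contact cluster-test results over
#' gray-matter contacts and reports, per participant and hemisphere: the
#' number of contacts, the percentage with significant modulation, the mean
#' (over significant contacts) of each contact's mean significant-cluster
#' frequency, the maximum p-value among significant contacts, and the mean
#' of the per-contact minimum and maximum significant frequencies.  A final
#' cohort row averages the per-row values.
#'
#' @param results named list of `cluster_test` objects, one per contact id.
#' @param contacts contact metadata (as in `seeg_recording$contacts` with a
#'   `participant_id` column, or a single recording's table plus
#'   `participant_id`).
#' @param participant_id used when `contacts` lacks a participant column.
#' @return A `modulation_summary` data frame with columns `participant`,
#'   `hemisphere`, `n_contacts`, `pct_significant`, `avg_freq`, `max_p`,
#'   `freq_lo`, `freq_hi`; the last row (`participant == "avg"`) holds
#'   cohort averages.
#' @export
summarize_modulation <- function(results, contacts, participant_id = NULL) {
  if (!"participant_id" %in% names(contacts)) {
    contacts$participant_id <- participant_id %||% "p01"
  }
  contacts <- contacts[contacts$tissue == "gray", , drop = FALSE]
  if (nrow(contacts) == 0) {
    warnf("no gray-matter contacts to summarize")
    return(empty_modulation_summary())
  }
  key <- interaction(contacts$participant_id, contacts$hemisphere, drop = TRUE)
  rows <- lapply(split(contacts, key), function(grp) {
    res <- results[grp$contact_id]
    have <- !vapply(res, is.null, logical(1))
    res <- res[have]
    sig <- vapply(res, function(r) isTRUE(r$significant), logical(1))
    n_sig <- sum(sig)
    row <- data.frame(
      participant = grp$participant_id[1],
      hemisphere = grp$hemisphere[1],
      n_contacts = nrow(grp),
      pct_significant = 100 * n_sig / max(nrow(grp), 1),
      avg_freq = NA_real_, max_p = NA_real_,
      freq_lo = NA_real_, freq_hi = NA_real_,
      stringsAsFactors = FALSE
    )
    if (n_sig > 0) {
      sres <- res[sig]
      los <- vapply(sres, function(r) r$significant_range[1], numeric(1))
      his <- vapply(sres, function(r) r$significant_range[2], numeric(1))
      row$avg_freq <- mean((los + his) / 2)
      row$max_p <- max(vapply(sres, function(r) r$p_value, numeric(1)))
      row$freq_lo <- mean(los)
      row$freq_hi <- mean(his)
    }
    row
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  avg <- data.frame(
    participant = "avg", hemisphere = "both",
    n_contacts = mean(out$n_contacts),
    pct_significant = mean(out$pct_significant),
    avg_freq = mean(out$avg_freq, na.rm = TRUE),
    max_p = mean(out$max_p, na.rm = TRUE),
    freq_lo = mean(out$freq_lo, na.rm = TRUE),
    freq_hi = mean(out$freq_hi, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  out <- rbind(out, avg)
  class(out) <- c("modulation_summary", "data.frame")
  out
}

empty_modulation_summary <- function() {
  out <- data.frame(participant = character(0), hemisphere = character(0),
                    n_contacts = numeric(0), pct_significant = numeric(0),
                    avg_freq = numeric(0), max_p = numeric(0),
                    freq_lo = numeric(0), freq_hi = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("modulation_summary", "data.frame")
  out
}

#' Yates-corrected two-proportion z-test
#'
#' Compares two independent proportions (e.g. the fraction of ipsilateral
#' vs. contralateral gray-matter contacts showing modulation) with the
#' pooled-variance z statistic and a continuity correction:
#' `z = max(|p1 - p2| - (1/n1 + 1/n2)/2, 0) / sqrt(p(1-p)(1/n1 + 1/n2))`.
#' The p-value is two-tailed; the statistic squared equals the
#' Yates-corrected chi-square of the 2 x 2 table.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @return A `proportion_test`: list with `k1`, `n1`, `k2`, `n2`, `p1`,
#'   `p2`, `z`, `p_value`.
#' @export
proportion_test <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stopf("invalid input: group sizes must be positive")
  if (k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    stopf("invalid input: counts must satisfy 0 <= k <= n")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pbar <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  num <- max(abs(p1 - p2) - (1 / n1 + 1 / n2) / 2, 0)
  z <- if (se == 0) 0 else num / se
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                 p1 = p1, p2 = p2, z = z,
                 p_value = 2 * stats::pnorm(-z)),
            class = "proportion_test")
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf("Two-proportion z-test (Yates-corrected): %d/%d (%.1f%%) vs %d/%d (%.1f%%)\n",
              x$k1, x$n1, 100 * x$p1, x$k2, x$n2, 100 * x$p2))
  cat(sprintf("  z = %.3f, two-tailed p = %.4g\n", x$z, x$p_value))
  invisible(x)
}
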