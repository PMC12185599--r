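# End-to-end orchestration: simulate/load -> line-noise removal -> spike
# detection -> weighted shaft re-referencing -> trial selection -> epoch
# extraction -> multitaper PSD -> outlier rejection -> cluster permutation
# contrasts -> cohort summaries and the laterality test.

#' Pipeline configuration
#'
#' All stage parameters in one validated object.  The defaults are the
#' analysis constants used throughout the package: 2000 Hz sampling, 60 Hz
#' line removal with 3 harmonics, 30 Hz / 30 microvolt spike detection,
#' 5 tapers with time-bandwidth product 3 on a grid of at most 0.3 Hz per
#' bin, the 13--30 Hz beta band, 10000 bootstrap resamples, 5000
#' permutations, and alpha 0.05.
#'
#' @param simulate a [cohort_spec()] to generate data in-memory, or `NULL`
#'   when reading from `data_dir`.
#' @param data_dir directory holding `<pid>.edf`, `<pid>_events.tsv`,
#'   `<pid>_contacts.tsv` (see [simulate_to_dir()]).
#' @param out_dir optional output directory for report tables.
#' @param line_f0,line_harmonics line-removal settings.
#' @param spike_hp_hz,spike_threshold_uv spike-detector settings.
#' @param n_tapers,nw multitaper settings.
#' @param max_bin_hz frequency-grid bound (Hz per bin).
#' @param band beta band in Hz.
#' @param n_boot bootstrap resamples (kept for report stages that use it).
#' @param n_perm permutations per cluster test.
#' @param alpha significance level.
#' @param rms_scope re-referencing weight scope, see [rereference_epochs()].
#' @param fmax_psd highest frequency retained in stored PSDs.
#' @param seed master seed for all pipeline randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = cohort_spec(), data_dir = NULL,
                            out_dir = NULL,
                            line_f0 = 60, line_harmonics = 3,
                            spike_hp_hz = 30, spike_threshold_uv = 30,
                            n_tapers = 5, nw = 3, max_bin_hz = 0.3,
                            band = c(13, 30), n_boot = 10000,
                            n_perm = 5000, alpha = 0.05,
                            rms_scope = "segment", fmax_psd = 100,
                            seed = 1L) {
  cfg <- list(simulate = simulate, data_dir = data_dir, out_dir = out_dir,
              line_f0 = line_f0, line_harmonics = line_harmonics,
              spike_hp_hz = spike_hp_hz,
              spike_threshold_uv = spike_threshold_uv,
              n_tapers = n_tapers, nw = nw, max_bin_hz = max_bin_hz,
              band = band, n_boot = n_boot, n_perm = n_perm, alpha = alpha,
              rms_scope = rms_scope, fmax_psd = fmax_psd,
              seed = as.integer(seed))
  if (is.null(cfg$simulate) && is.null(cfg$data_dir)) {
    stopf("either a simulation spec or a data directory is required")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_contrasts <- function() {
  data.frame(
    name = c("fixation_gt_delay", "fixation_gt_response", "delay_vs_response"),
    phase_a = c("Fixation", "Fixation", "Delay"),
    phase_b = c("Delay", "Response", "Response"),
    tail = c("one", "one", "two"),
    stringsAsFactors = FALSE
  )
}

# Trials (row indices of the phase's epoch array) whose analysis window
# overlaps a detected spike on the given channel.
spike_overlap_rows <- function(phase_info, events, pad = 0.05) {
  if (is.null(events) || nrow(events) == 0) return(integer(0))
  t0 <- phase_info$start_s - pad
  t1 <- phase_info$start_s + phase_info$duration_s + pad
  which(vapply(seq_along(t0), function(i) {
    any(events$peak_s >= t0[i] & events$peak_s <= t1[i])
  }, logical(1)))
}

#' Analyze a single participant
#'
#' Runs the preprocessing, spectral and statistical stages for one
#' recording/log pair.  See [run_pipeline()] for the stage order.
#'
#' @param rec a `seeg_recording` (raw, line noise still present).
#' @param log the matching `session_log`.
#' @param config a [pipeline_config()].
#' @param participant_index used to derive per-participant seeds.
#' @return A list with `behavior`, `selection`, `spiky`, `kept_per_phase`,
#'   `tests` (per contrast, named by contact id), `contacts`, `counts`.
#' @export
analyze_participant <- function(rec, log, config = pipeline_config(),
                                participant_index = 1L) {
  rec <- remove_line_noise(rec, f0 = config$line_f0,
                           n_harmonics = config$line_harmonics)
  spikes <- detect_spikes(rec, hp_cutoff = config$spike_hp_hz,
                          threshold_uv = config$spike_threshold_uv)
  spiky <- spiky_channels(spikes)
  sel <- select_trials(log)
  behavior <- compute_behavior(log)
  behavior$trials_after_outlier_removal <- length(sel$kept)
  out <- list(behavior = behavior, selection = sel, spiky = spiky,
              participant_id = rec$participant_id,
              contacts = rec$contacts, tests = NULL,
              counts = list(n_trials = nrow(log),
                            trials_kept = length(sel$kept),
                            trials_dropped = nrow(log) - length(sel$kept),
                            n_contacts = nrow(rec$contacts)))
  if (sel$run_discarded) {
    out$run_discarded <- TRUE
    return(out)
  }
  out$run_discarded <- FALSE
  epochs <- extract_phase_epochs(rec, log, sel$kept)
  epochs <- suppressWarnings(
    rereference_epochs(epochs, exclude = spiky, rms_scope = config$rms_scope)
  )
  contacts <- rec$contacts
  contrasts <- pipeline_contrasts()
  phases_needed <- unique(c(contrasts$phase_a, contrasts$phase_b))
  # per channel-phase: PSD and surviving trial ids
  psds <- list()
  kept_ids <- list()
  for (ph in phases_needed) {
    info <- epochs$phases[[ph]]
    for (j in seq_len(nrow(contacts))) {
      cid <- contacts$contact_id[j]
      m <- channel_epochs(epochs, ph, cid)
      psd <- compute_psd(m, fs = epochs$fs, n_tapers = config$n_tapers,
                         nw = config$nw, fmax = config$fmax_psd)
      rej <- suppressWarnings(reject_outlier_trials(
        m, psd, spike_trials = spike_overlap_rows(info, spikes[[cid]]),
        band = config$band))
      key <- paste(ph, cid, sep = "|")
      psds[[key]] <- psd
      kept_ids[[key]] <- info$trials[rej$kept]
    }
  }
  tests <- list()
  for (r in seq_len(nrow(contrasts))) {
    cname <- contrasts$name[r]
    tests[[cname]] <- stats::setNames(
      vector("list", nrow(contacts)), contacts$contact_id)
    for (j in seq_len(nrow(contacts))) {
      cid <- contacts$contact_id[j]
      ka <- paste(contrasts$phase_a[r], cid, sep = "|")
      kb <- paste(contrasts$phase_b[r], cid, sep = "|")
      paired <- intersect(kept_ids[[ka]], kept_ids[[kb]])
      if (length(paired) < 5) next
      ra <- match(paired, epochs$phases[[contrasts$phase_a[r]]]$trials)
      rb <- match(paired, epochs$phases[[contrasts$phase_b[r]]]$trials)
      tests[[cname]][[cid]] <- cluster_permutation_test(
        psds[[ka]]$power[ra, , drop = FALSE],
        psds[[kb]]$power[rb, , drop = FALSE],
        tail = contrasts$tail[r], n_perm = config$n_perm,
        seed = child_seed(config$seed, 1000L * participant_index + 10L * j + r),
        band = config$band, alpha = config$alpha,
        freqs = psds[[ka]]$freqs)
    }
  }
  out$tests <- tests
  out
}

#' Run the full pipeline over a cohort
#'
#' Stage order per participant: line-noise removal, interictal spike
#' detection, RMS-weighted shaft re-referencing (spiky channels excluded
#' from the weights), trial selection (Response-duration rules plus the 50%
#' run-discard rule), per-phase epoch extraction, multitaper PSD, two-stage
#' IQR outlier rejection, then the three phase contrasts
#' (Fixation > Delay and Fixation > Response one-tailed, Delay vs. Response
#' two-tailed) as frequency-cluster permutation tests over the beta band.
#' Cohort tables summarize per-contact modulation per participant and
#' hemisphere, and the laterality comparison applies the Yates-corrected
#' two-proportion z-test to ipsilateral vs. contralateral gray-matter
#' contacts.
#'
#' @param config a [pipeline_config()].
#' @return A `run_report`: list with `behavior` (per-participant table),
#'   `modulation` (one `modulation_summary` per contrast), `laterality`
#'   (proportion tests for the two baseline contrasts), `recovery`
#'   (sensitivity/false-positive rate against ground truth, simulate mode
#'   only), `counts`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  participants <- pipeline_inputs(config)
  results <- vector("list", length(participants$ids))
  truths <- list()
  for (i in seq_along(participants$ids)) {
    p <- participants$load(i)
    truths[[p$participant_id]] <- p$truth
    results[[i]] <- analyze_participant(p$recording, p$log, config,
                                        participant_index = i)
  }
  build_report(results, truths, config)
}

pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    spec <- config$simulate
    list(ids = sprintf("p%02d", seq_len(spec$n_participants)),
         load = function(i) simulate_participant(spec, i))
  } else {
    edfs <- sort(list.files(config$data_dir, pattern = "\\.edf$",
                            full.names = TRUE))
    if (length(edfs) == 0) stopf("no EDF files found in %s", config$data_dir)
    ids <- sub("\\.edf$", "", basename(edfs))
    list(ids = ids, load = function(i) {
      pid <- ids[i]
      ct <- read_contacts_tsv(file.path(config$data_dir,
                                        paste0(pid, "_contacts.tsv")))
      rec <- read_edf(edfs[i], contacts = ct)
      log <- read_events_tsv(file.path(config$data_dir,
                                       paste0(pid, "_events.tsv")),
                             participant_id = pid)
      tj <- file.path(config$data_dir, paste0(pid, "_truth.json"))
      truth <- if (file.exists(tj)) read_truth_json(tj) else NULL
      list(recording = rec, log = log, truth = truth, participant_id = pid)
    })
  }
}

build_report <- function(results, truths, config) {
  behavior <- do.call(rbind, lapply(results, function(r) {
    b <- r$behavior
    data.frame(participant = r$participant_id,
               success_rate = b$success_rate,
               mean_delay_time = b$mean_delay_time,
               mean_movement_time = b$mean_movement_time,
               mean_trial_time = b$mean_trial_time,
               total_trials = b$total_trials,
               trials_after_outlier_removal = b$trials_after_outlier_removal,
               run_discarded = r$run_discarded,
               stringsAsFactors = FALSE)
  }))
  analyzed <- Filter(function(r) !r$run_discarded, results)
  all_contacts <- do.call(rbind, lapply(analyzed, function(r) {
    ct <- r$contacts
    ct$participant_id <- r$participant_id
    ct
  }))
  modulation <- list()
  contact_flags <- list()
  for (cname in pipeline_contrasts()$name) {
    tests <- stats::setNames(
      do.call(c, lapply(analyzed, function(r) unname(r$tests[[cname]]))),
      do.call(c, lapply(analyzed, function(r) names(r$tests[[cname]])))
    )
    modulation[[cname]] <- if (is.null(all_contacts)) {
      empty_modulation_summary()
    } else {
      suppressWarnings(summarize_modulation(tests, all_contacts))
    }
    contact_flags[[cname]] <- vapply(tests, function(t) {
      !is.null(t) && isTRUE(t$significant)
    }, logical(1))
  }
  laterality <- list()
  if (!is.null(all_contacts)) {
    gray <- all_contacts[all_contacts$tissue == "gray", ]
    for (cname in c("fixation_gt_delay", "fixation_gt_response")) {
      sig <- contact_flags[[cname]][gray$contact_id]
      sig[is.na(sig)] <- FALSE
      ip <- gray$laterality == "ipsilateral"
      if (any(ip) && any(!ip)) {
        laterality[[cname]] <- proportion_test(sum(sig[ip]), sum(ip),
                                               sum(sig[!ip]), sum(!ip))
      }
    }
  }
  recovery <- NULL
  if (length(truths) > 0 && !all(vapply(truths, is.null, logical(1))) &&
      !is.null(all_contacts)) {
    gray <- all_contacts[all_contacts$tissue == "gray", ]
    erd <- unlist(lapply(truths, function(t) t$erd_contacts))
    sig <- contact_flags[["fixation_gt_delay"]][gray$contact_id]
    sig[is.na(sig)] <- FALSE
    is_erd <- gray$contact_id %in% erd
    recovery <- list(
      sensitivity = if (any(is_erd)) mean(sig[is_erd]) else NA_real_,
      false_positive_rate = if (any(!is_erd)) mean(sig[!is_erd]) else NA_real_,
      n_erd = sum(is_erd), n_non_erd = sum(!is_erd)
    )
  }
  counts <- list(
    n_participants = length(results),
    n_runs_discarded = sum(vapply(results, function(r) r$run_discarded,
                                  logical(1))),
    trials_total = sum(behavior$total_trials),
    trials_kept = sum(vapply(results, function(r) r$counts$trials_kept, numeric(1))),
    trials_dropped = sum(vapply(results, function(r) r$counts$trials_dropped, numeric(1))),
    contacts_analyzed = if (is.null(all_contacts)) 0 else nrow(all_contacts)
  )
  report <- structure(
    list(behavior = behavior, modulation = modulation,
         laterality = laterality, recovery = recovery, counts = counts,
         provenance = list(seed = config$seed,
                           n_perm = config$n_perm, alpha = config$alpha,
                           band = config$band,
                           package_version = as.character(utils::packageVersion("seegerd")),
                           r_version = R.version.string)),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write report tables to a directory
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  for (cname in names(report$modulation)) {
    utils::write.csv(as.data.frame(report$modulation[[cname]]),
                     file.path(dir, paste0("modulation_", cname, ".csv")),
                     row.names = FALSE)
  }
  if (length(report$laterality) > 0) {
    lat <- do.call(rbind, lapply(names(report$laterality), function(cn) {
      t <- report$laterality[[cn]]
      data.frame(contrast = cn, k_ipsi = t$k1, n_ipsi = t$n1,
                 k_contra = t$k2, n_contra = t$n2,
                 pct_ipsi = 100 * t$p1, pct_contra = 100 * t$p2,
                 z = t$z, p_value = t$p_value, stringsAsFactors = FALSE)
    }))
    utils::write.csv(lat, file.path(dir, "laterality.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(counts = report$counts, recovery = report$recovery,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Validate pipeline inputs
#'
#' Checks channel/metadata agreement, sampling rate, event monotonicity and
#' phase-duration ranges against the task template.  Violations are
#' returned, not thrown; `level` is `"error"` for hard failures and
#' `"warning"` for recoverable ones.
#'
#' @param rec a `seeg_recording`.
#' @param log a `session_log`.
#' @return Data frame with columns `level`, `message` (zero rows when
#'   everything checks out).
#' @export
validate_inputs <- function(rec, log) {
  v <- list()
  add <- function(level, msg) v[[length(v) + 1]] <<- data.frame(
    level = level, message = msg, stringsAsFactors = FALSE)
  if (ncol(rec$samples) != nrow(rec$contacts)) {
    add("error", "channel count does not match contact metadata")
  }
  if (!all(is.finite(rec$samples))) add("error", "non-finite sample values")
  if (rec$fs <= 0) add("error", "non-positive sampling rate")
  else if (rec$fs != 2000) add("warning",
    sprintf("sampling rate %g Hz differs from the 2000 Hz default; parameters rescale", rec$fs))
  onsets <- log$iti_onset
  if (any(diff(onsets) <= 0)) add("error", "trial onsets not strictly increasing")
  tmpl <- phase_template()
  for (r in seq_len(nrow(tmpl))) {
    d <- log[[paste0(tolower(tmpl$phase[r]), "_duration")]]
    if (any(d < tmpl$min_s[r] - 1e-6 | d > tmpl$max_s[r] + 1e-6)) {
      add("warning", sprintf("%s durations outside the task template [%g, %g] s",
                             tmpl$phase[r], tmpl$min_s[r], tmpl$max_s[r]))
    }
  }
  # contiguity: each phase must start where the previous ends
  phs <- task_phases()
  for (i in seq_len(length(phs) - 1)) {
    end_i <- log[[paste0(tolower(phs[i]), "_onset")]] +
      log[[paste0(tolower(phs[i]), "_duration")]]
    start_next <- log[[paste0(tolower(phs[i + 1]), "_onset")]]
    if (any(abs(end_i - start_next) > 1e-6)) {
      add("error", sprintf("%s and %s phases overlap or leave gaps",
                           phs[i], phs[i + 1]))
      break
    }
  }
  if (length(v) == 0) {
    data.frame(level = character(0), message = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d participant(s), %d run(s) discarded, %d contacts analyzed\n",
              x$counts$n_participants, x$counts$n_runs_discarded,
              x$counts$contacts_analyzed))
  cat(sprintf("  mean success rate %.1f%%\n", mean(x$behavior$success_rate)))
  for (cname in names(x$modulation)) {
    m <- x$modulation[[cname]]
    if (nrow(m) > 0) {
      avg <- m[m$participant == "avg", ]
      cat(sprintf("  %s: %.1f%% of gray contacts significant\n",
                  cname, avg$pct_significant))
    }
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  ground-truth recovery: sensitivity %.2f, false-positive rate %.2f\n",
                x$recovery$sensitivity, x$recovery$false_positive_rate))
  }
  invisible(x)
}
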