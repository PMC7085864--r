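# Recording-level preprocessing: duration filter, dialect downsampling,
# facilitation rejection, maximum-amplitude selection, artifact trimming.

STANDARD_RATE_HZ <- 19200
STANDARD_N <- 1920
ARTIFACT_SAMPLES <- 70L

#' Default facilitation power threshold (mV^2)
#'
#' Mean squared deviation (about the segment mean) of the pre-latency
#' segment above which a recording is considered facilitated, i.e.
#' contaminated by voluntary baseline muscle contraction. The value is
#' calibrated on the synthetic cohort generator: quiescent recordings have
#' a pre-latency power around `noise_sd^2` plus the colored background
#' component (about 2.5e-4 mV^2 at default settings), while facilitated
#' recordings carry an additional high-pass contraction component an order
#' of magnitude stronger (about 4e-3 mV^2); 8e-4 sits between the two
#' populations on a log scale.
#' @export
FACILITATION_THRESHOLD_DEFAULT <- 8e-4

#' Peak-to-peak amplitude of a recording
#'
#' The difference between the maximum and the minimum value of the whole
#' trace, in millivolts.
#'
#' @param ts An [mep_ts] or a numeric vector.
#' @return A non-negative scalar (mV).
#' @export
peak_to_peak <- function(ts) {
  x <- ts_samples(ts)
  if (length(x) == 0L) stop("empty recording", call. = FALSE)
  max(x) - min(x)
}

#' Downsample a recording to the standard dialect
#'
#' Recordings digitized at 20 kHz (2000 samples over 100 ms) are mapped by
#' linear interpolation onto the 1920 uniformly spaced time points of the
#' 19.2 kHz dialect. Recordings already at 19.2 kHz are returned unchanged.
#' The MEP signal band lies far below the Nyquist frequency of either
#' dialect, so linear interpolation preserves the waveform; a 200 Hz
#' component loses less than 1% amplitude.
#'
#' @param ts An [mep_ts] with 1920 or 2000 samples.
#' @return An [mep_ts] with 1920 samples at 19.2 kHz.
#' @export
resample_to_standard <- function(ts) {
  if (!inherits(ts, "mep_ts")) stop("'ts' must be an mep_ts", call. = FALSE)
  n <- length(ts$samples)
  if (n == STANDARD_N && ts$sampling_rate_hz == STANDARD_RATE_HZ) {
    return(ts)
  }
  if (n != 2000L) {
    stop(sprintf("unsupported dialect: %d samples @ %.0f Hz", n,
                 ts$sampling_rate_hz), call. = FALSE)
  }
  t_in <- (seq_len(n) - 1) / ts$sampling_rate_hz
  t_out <- (seq_len(STANDARD_N) - 1) / STANDARD_RATE_HZ
  out <- stats::approx(t_in, ts$samples, xout = t_out, rule = 2)$y
  ts$samples <- out
  ts$sampling_rate_hz <- STANDARD_RATE_HZ
  ts
}

#' Detect a facilitated (baseline-contracted) recording
#'
#' Facilitated measurements are characterized by a non-flat signal right
#' from the start. The detector computes the power (mean squared deviation
#' from the segment mean) of the segment between the end of the stimulus
#' artifact (sample 70) and the earliest physiological latency (17 ms, the
#' lower bound for the hands; the same floor is used for the feet, whose
#' lower bound is higher). The artifact samples are excluded because the
#' stimulation transient would otherwise dominate the power estimate.
#'
#' @param ts An [mep_ts] at the standard 19.2 kHz rate.
#' @param latency_floor_ms End of the examined segment, default 17 ms.
#' @param power_threshold Power threshold in mV^2; see
#'   [FACILITATION_THRESHOLD_DEFAULT].
#' @return `TRUE` if the recording is flagged as facilitated.
#' @export
detect_facilitation <- function(ts, latency_floor_ms = 17,
                                power_threshold = FACILITATION_THRESHOLD_DEFAULT) {
  if (!is.numeric(power_threshold) || power_threshold <= 0) {
    stop("'power_threshold' must be positive", call. = FALSE)
  }
  x <- ts_samples(ts)
  rate <- if (inherits(ts, "mep_ts")) ts$sampling_rate_hz else STANDARD_RATE_HZ
  end <- floor(latency_floor_ms / 1000 * rate)  # 0-based exclusive end
  if (end <= ARTIFACT_SAMPLES + 1L) {
    stop("latency floor lies inside the artifact window", call. = FALSE)
  }
  seg <- x[(ARTIFACT_SAMPLES + 1L):end]  # 0-based samples [70, end)
  power <- mean((seg - mean(seg))^2)
  is.finite(power) && power > power_threshold
}

#' Select the maximum-amplitude recording for one limb
#'
#' Of the recordings taken at increasing stimulator output for one limb at
#' one visit, only the one with the maximal peak-to-peak amplitude is kept,
#' as it is the most informative response. Exact ties are broken in favor
#' of the lowest excitation strength (the physiologically earlier
#' response).
#'
#' @param recordings A list of [mep_ts] for a single (visit, anatomy, side).
#' @return The selected [mep_ts].
#' @export
select_max_amplitude <- function(recordings) {
  if (length(recordings) == 0L) {
    stop("no recordings available for this limb", call. = FALSE)
  }
  p2p <- vapply(recordings, peak_to_peak, numeric(1))
  best <- which(p2p == max(p2p))
  if (length(best) > 1L) {
    exc <- vapply(recordings[best], function(r) r$excitation_pct, numeric(1))
    best <- best[order(exc, seq_along(best))][1L]
  }
  recordings[[best[1L]]]
}

#' Trim the stimulus artifact
#'
#' The first 70 samples of each trace contain the electrophysiological
#' stimulation artifact and are discarded before feature extraction,
#' leaving 1850 samples of a standard 1920-sample recording.
#'
#' @param ts An [mep_ts] or numeric vector.
#' @param n_trim Number of leading samples to drop (default 70).
#' @return Numeric vector of the remaining samples, order preserved.
#' @export
trim_artifact <- function(ts, n_trim = ARTIFACT_SAMPLES) {
  x <- ts_samples(ts)
  if (length(x) <= n_trim) {
    stop(sprintf("recording has %d samples; cannot trim %d", length(x),
                 n_trim), call. = FALSE)
  }
  x[(n_trim + 1L):length(x)]
}

#' Apply the recording-level filters to a cohort
#'
#' Runs, in order: the duration filter (recordings not spanning 100 ms are
#' dropped), downsampling of the 20 kHz dialect to 19.2 kHz, facilitation
#' rejection, per-limb maximum-amplitude selection, and the completeness
#' filter (visits without all four limb recordings are dropped). Each
#' filter's row counts are recorded in the `filter_log` attribute so the
#' cohort accounting chain stays auditable.
#'
#' @param cohort An [mep_cohort].
#' @param facilitation_threshold Power threshold passed to
#'   [detect_facilitation()].
#' @param duration_tol_ms Tolerance on the 100 ms duration check.
#' @return The cohort with one standard-rate recording per (visit, limb)
#'   and only complete visits retained; carries a `filter_log` attribute.
#' @export
preprocess_cohort <- function(cohort,
                              facilitation_threshold = FACILITATION_THRESHOLD_DEFAULT,
                              duration_tol_ms = 0.5) {
  stopifnot(inherits(cohort, "mep_cohort"))
  rec <- cohort$recordings
  log <- list()
  note <- function(stage, before, after, reason) {
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, rows_before = before, rows_after = after,
      reason = reason, stringsAsFactors = FALSE)
  }

  # 1. duration filter
  n0 <- nrow(rec)
  dur <- rec$n_samples / rec$sampling_rate_hz * 1000
  rec <- rec[abs(dur - 100) <= duration_tol_ms, , drop = FALSE]
  note("duration_filter", n0, nrow(rec), "duration != 100 ms")

  # 2. downsample the 20 kHz dialect
  needs <- rec$recording_id[rec$n_samples != STANDARD_N]
  for (id in needs) {
    ts <- cohort_recording(cohort, id, meta = rec)
    ts <- resample_to_standard(ts)
    cohort$samples[[id]] <- ts$samples
    rec$n_samples[rec$recording_id == id] <- STANDARD_N
    rec$sampling_rate_hz[rec$recording_id == id] <- STANDARD_RATE_HZ
  }
  note("resample", nrow(rec), nrow(rec),
       sprintf("%d recordings downsampled to 1920 samples", length(needs)))

  # 3. facilitation rejection
  n0 <- nrow(rec)
  fac <- vapply(rec$recording_id, function(id) {
    detect_facilitation(cohort_recording(cohort, id, meta = rec),
                        power_threshold = facilitation_threshold)
  }, logical(1))
  rec <- rec[!fac, , drop = FALSE]
  note("facilitation_filter", n0, nrow(rec), "pre-latency power above threshold")

  # 4. per-limb maximum-amplitude selection
  n0 <- nrow(rec)
  key <- paste(rec$visit_id, rec$anatomy, rec$side, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(rec)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    tss <- lapply(rec$recording_id[idx], cohort_recording, cohort = cohort,
                  meta = rec)
    sel <- select_max_amplitude(tss)
    idx[match(TRUE, vapply(tss, identical, logical(1), sel))]
  }), use.names = FALSE)
  rec <- rec[sort(keep), , drop = FALSE]
  note("max_amplitude_selection", n0, nrow(rec),
       "kept the maximal peak-to-peak recording per limb")

  # 5. visit completeness: all 4 limbs present
  n_visits0 <- nrow(cohort$visits)
  limb_count <- tapply(paste(rec$anatomy, rec$side),
                       rec$visit_id,
                       function(v) length(unique(v)))
  complete <- names(limb_count)[limb_count == 4L]
  cohort$visits <- cohort$visits[cohort$visits$visit_id %in% complete, ,
                                 drop = FALSE]
  rec <- rec[rec$visit_id %in% complete, , drop = FALSE]
  note("visit_completeness", n_visits0, nrow(cohort$visits),
       "visits lacking one of APB L/R, AH L/R dropped")

  cohort$recordings <- rec
  cohort$samples <- cohort$samples[rec$recording_id]
  attr(cohort, "filter_log") <- do.call(rbind, log)
  attr(cohort, "preprocessed") <- TRUE
  cohort
}

#' Retain only visits with a complete set of limb recordings
#'
#' @param visits Visit table with a `visit_id` column.
#' @param recordings Recording metadata table with `visit_id`, `anatomy`,
#'   `side` and a duration; recordings not spanning 100 ms are ignored.
#' @return The retained subset of `visits`.
#' @export
filter_visits <- function(visits, recordings) {
  dur <- recordings$n_samples / recordings$sampling_rate_hz * 1000
  rec <- recordings[abs(dur - 100) <= 0.5, , drop = FALSE]
  limb_count <- tapply(paste(rec$anatomy, rec$side), rec$visit_id,
                       function(v) length(unique(v)))
  complete <- names(limb_count)[limb_count == 4L]
  visits[visits$visit_id %in% complete, , drop = FALSE]
}

# Materialize one recording of a cohort as an mep_ts.
cohort_recording <- function(cohort, recording_id, meta = cohort$recordings) {
  i <- match(recording_id, meta$recording_id)
  if (is.na(i)) stop(sprintf("unknown recording '%s'", recording_id),
                     call. = FALSE)
  mep_ts(cohort$samples[[recording_id]], meta$sampling_rate_hz[i],
         anatomy = meta$anatomy[i], side = meta$side[i],
         excitation_pct = meta$excitation_pct[i],
         visit_ref = meta$visit_id[i])
}
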