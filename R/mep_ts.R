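#' Construct a single evoked-potential time series (EPTS)
#'
#' An `mep_ts` holds one limb recording of a motor evoked potential: the
#' sampled voltage trace (millivolts), its sampling rate and the anatomical
#' annotations. Two machine dialects occur in practice: 2000 samples at
#' 20 kHz and 1920 samples at 19.2 kHz, both spanning 100 ms from the
#' moment of cortical stimulation.
#'
#' @param samples Numeric vector of voltages in millivolts, ordered in time.
#'   Sample `i` (0-based) covers the interval `[i/rate, (i+1)/rate)`.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param anatomy `"APB"` (abductor pollicis brevis, hand) or `"AH"`
#'   (abductor hallucis, foot).
#' @param side `"L"` or `"R"`.
#' @param excitation_pct Stimulator output in percent of maximum.
#' @param visit_ref Identifier of the visit the recording belongs to.
#'
#' @return An object of class `mep_ts`.
#' @export
mep_ts <- function(samples, sampling_rate_hz, anatomy = c("APB", "AH"),
                   side = c("L", "R"), excitation_pct = NA_real_,
                   visit_ref = NA_character_) {
  anatomy <- match.arg(anatomy)
  side <- match.arg(side)
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("'samples' must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("'sampling_rate_hz' must be a positive number", call. = FALSE)
  }
  structure(
    list(
      samples = as.numeric(samples),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      anatomy = anatomy,
      side = side,
      excitation_pct = as.numeric(excitation_pct),
      visit_ref = as.character(visit_ref)
    ),
    class = "mep_ts"
  )
}

#' @export
print.mep_ts <- function(x, ...) {
  cat(sprintf("<mep_ts> %s %s: %d samples @ %.1f kHz (%.1f ms), visit %s\n",
              x$anatomy, x$side, length(x$samples),
              x$sampling_rate_hz / 1000, duration_ms(x), x$visit_ref))
  invisible(x)
}

#' @export
plot.mep_ts <- function(x, ...) {
  t_ms <- (seq_along(x$samples) - 1) / x$sampling_rate_hz * 1000
  graphics::plot(t_ms, x$samples, type = "l", xlab = "time (ms)",
                 ylab = "amplitude (mV)",
                 main = sprintf("MEP %s %s", x$anatomy, x$side), ...)
  invisible(x)
}

#' Duration of a recording in milliseconds
#'
#' @param ts An [mep_ts].
#' @return Scalar duration (ms); 100 for both standard dialects.
#' @export
duration_ms <- function(ts) {
  length(ts$samples) / ts$sampling_rate_hz * 1000
}

ts_samples <- function(x) {
  if (inherits(x, "mep_ts")) x$samples else as.numeric(x)
}
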