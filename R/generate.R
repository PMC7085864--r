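# Synthetic MEP cohort generator with known ground truth.
#
# The waveform model: a damped oscillatory stimulus artifact over roughly
# the first 70 samples; an amplitude-scaled biphasic Gabor-like response
# wave starting at the latency; a slow return-to-zero tail after the
# response (its time constant drives the sliding-window dispersion
# feature); an AR(1) colored background component (its coefficient drives
# the AR-residual autocorrelation feature); additive white measurement
# noise; and, for facilitated recordings, band-limited (>100 Hz)
# contraction noise across the whole window. A shared per-visit severity
# latent couples latency slowing, tail time constant and background
# coloring across all four limbs, reflecting bilateral involvement.

#' Configuration of a synthetic MEP cohort
#'
#' Defaults emulate the reference clinical cohort: 419 patients with a
#' handful of qualifying visits each (about 2500 visits in total), 11%
#' two-year progression prevalence, age 45 (SD 12) years, baseline EDSS
#' 3.0 (SD 1.8), hand (APB) latencies in 19-32 ms (physiological lower
#' bound 17 ms), foot (AH) latencies in 30-45 ms, response amplitudes up
#' to 1 mV, and a 20% share of the 2000-sample 20 kHz machine dialect.
#'
#' @param n_patients Number of patients.
#' @param visits_per_patient Integer range `c(min, max)` of qualifying
#'   visits per patient.
#' @param prevalence Probability of two-year disability progression.
#' @param latency_range_ms Named list with `APB` and `AH` latency
#'   intervals (ms); the APB lower bound must respect the 17 ms
#'   physiological floor.
#' @param amplitude_range_mv Peak-to-peak response amplitude interval (mV).
#' @param noise_sd_mv White measurement noise SD (mV).
#' @param facilitation_rate Probability that a limb recording is
#'   facilitated (and hence rejected by preprocessing).
#' @param machine_mix Probability of the 2000-sample 20 kHz dialect.
#' @param coupling Named numeric vector of coefficients driving the
#'   progression label through a logistic link on standardized feature
#'   values. Names are `"latency"` (mean true latency over the four
#'   limbs) or `"<anatomy>_<catalog feature>"` with anatomy `apb`/`ah`,
#'   e.g. `"apb_sw_disp_w50_s25"` (left+right sum of the
#'   robust-sigmoid-normalized feature, the representation the analysis
#'   pipeline works with).
#'   The default signs are aligned with the shared severity latent
#'   (which raises latency and the dispersion feature but lowers the
#'   AR-residual feature), so no driver's marginal association with the
#'   label is cancelled by its correlation with the others.
#' @param nonlinear_coupling If `TRUE`, the linear predictor is
#'   dominated by an interaction term between the first two coupled
#'   features (the additive part is attenuated). The product of two
#'   near-symmetric standardized features is linearly invisible, so this
#'   regime separates classifiers that can represent interactions
#'   (random forests) from those that cannot (logistic regression).
#' @param dropout_rate Probability that a visit lacks its two-year
#'   follow-up EDSS measurement.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated `cohort_config`.
#' @export
cohort_config <- function(n_patients = 419L,
                          visits_per_patient = c(2L, 10L),
                          prevalence = 0.11,
                          latency_range_ms = list(APB = c(19, 32),
                                                  AH = c(30, 45)),
                          amplitude_range_mv = c(0.2, 1.0),
                          noise_sd_mv = 0.01,
                          facilitation_rate = 0.05,
                          machine_mix = 0.2,
                          coupling = c(latency = 0.9,
                                       apb_sw_disp_w50_s25 = 0.7,
                                       ah_ar2_resid_ac1 = -0.7),
                          nonlinear_coupling = FALSE,
                          dropout_rate = 0,
                          seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1L) {
    stop("'n_patients' must be at least 1", call. = FALSE)
  }
  stopifnot_scalar_prob(prevalence, "prevalence")
  stopifnot_scalar_prob(facilitation_rate, "facilitation_rate")
  stopifnot_scalar_prob(machine_mix, "machine_mix")
  stopifnot_scalar_prob(dropout_rate, "dropout_rate")
  if (length(visits_per_patient) != 2L ||
      visits_per_patient[1] > visits_per_patient[2] ||
      visits_per_patient[1] < 1L) {
    stop("'visits_per_patient' must be a non-empty positive range",
         call. = FALSE)
  }
  for (an in c("APB", "AH")) {
    r <- latency_range_ms[[an]]
    if (is.null(r) || length(r) != 2L || r[1] >= r[2]) {
      stop(sprintf("latency range for %s must be a non-empty interval", an),
           call. = FALSE)
    }
  }
  if (latency_range_ms$APB[1] < 17) {
    stop("hand (APB) latencies below the 17 ms physiological floor",
         call. = FALSE)
  }
  if (amplitude_range_mv[1] <= 0 ||
      amplitude_range_mv[1] > amplitude_range_mv[2]) {
    stop("'amplitude_range_mv' must be a positive non-empty interval",
         call. = FALSE)
  }
  if (!is.null(coupling) && length(coupling) &&
      is.null(names(coupling))) {
    stop("'coupling' must be a named coefficient vector", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 visits_per_patient = as.integer(visits_per_patient),
                 prevalence = prevalence,
                 latency_range_ms = latency_range_ms,
                 amplitude_range_mv = amplitude_range_mv,
                 noise_sd_mv = noise_sd_mv,
                 facilitation_rate = facilitation_rate,
                 machine_mix = machine_mix,
                 coupling = coupling,
                 nonlinear_coupling = isTRUE(nonlinear_coupling),
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

MEP_DIALECTS <- list(
  "19.2kHz" = list(n = 1920L, rate = 19200),
  "20kHz" = list(n = 2000L, rate = 20000)
)

#' Generate a single synthetic MEP recording
#'
#' Draws from the current RNG stream (seed it with `set.seed()` for
#' reproducibility). The deterministic part of the waveform (response
#' plus return-to-zero tail) is rescaled so its peak-to-peak equals
#' `amplitude_mv` exactly; the stimulus artifact is scaled below the
#' response extremes so the whole-trace peak-to-peak reflects the
#' response, as it does on the recording machines.
#'
#' @param latency_ms Response onset in ms; must lie after the artifact
#'   window and leave room for the response before 100 ms.
#' @param amplitude_mv Target peak-to-peak response amplitude (mV), > 0.
#' @param facilitated Add baseline muscle-contraction noise across the
#'   whole window.
#' @param dialect `"19.2kHz"` (1920 samples) or `"20kHz"` (2000 samples).
#' @param noise_sd_mv White noise SD.
#' @param tail_tau_ms Time constant of the post-response return-to-zero
#'   tail.
#' @param ar_phi AR(1) coefficient of the colored background component.
#' @param ar_sd_mv Marginal SD of the colored background component.
#' @param facilitation_sd_mv SD of the contraction noise when
#'   facilitated.
#' @param anatomy,side,excitation_pct,visit_ref Annotations stored on the
#'   recording.
#' @return An [mep_ts]; the true generating parameters are attached as
#'   attributes (`true_latency_ms`, `facilitated`).
#' @export
generate_mep <- function(latency_ms, amplitude_mv, facilitated = FALSE,
                         dialect = c("19.2kHz", "20kHz"),
                         noise_sd_mv = 0.01, tail_tau_ms = 12,
                         ar_phi = 0.6, ar_sd_mv = 0.012,
                         facilitation_sd_mv = 0.06,
                         anatomy = "APB", side = "L",
                         excitation_pct = 50, visit_ref = NA_character_) {
  dialect <- match.arg(dialect)
  d <- MEP_DIALECTS[[dialect]]
  artifact_end_ms <- ARTIFACT_SAMPLES / STANDARD_RATE_HZ * 1000
  if (!is.numeric(latency_ms) || latency_ms <= artifact_end_ms ||
      latency_ms > 85) {
    stop(sprintf("latency %.1f ms outside the valid window (%.1f, 85] ms",
                 latency_ms, artifact_end_ms), call. = FALSE)
  }
  if (!is.numeric(amplitude_mv) || amplitude_mv <= 0) {
    stop("'amplitude_mv' must be positive", call. = FALSE)
  }
  t_ms <- (seq_len(d$n) - 1) / d$rate * 1000

  # stimulus artifact: damped 1.5 kHz oscillation, gone by sample 70
  artifact <- 0.45 * amplitude_mv * exp(-t_ms / 0.5) *
    sin(2 * pi * 1.5 * t_ms)

  # biphasic compound-muscle-action-potential wave
  sigma <- 2.5
  tc <- latency_ms + 3 * sigma
  resp <- exp(-((t_ms - tc)^2) / (2 * sigma^2)) *
    sin(2 * pi * 0.15 * (t_ms - tc))

  # slow return-to-zero tail after the response
  dt <- t_ms - latency_ms
  tail_wave <- ifelse(dt > 0,
                      (1 - exp(-dt / 2)) * exp(-dt / tail_tau_ms), 0)
  shape <- resp + 0.35 * tail_wave
  shape <- shape * amplitude_mv / (max(shape) - min(shape))

  colored <- as.numeric(stats::filter(
    stats::rnorm(d$n, 0, ar_sd_mv * sqrt(1 - ar_phi^2)),
    ar_phi, method = "recursive"))
  x <- artifact + shape + colored + stats::rnorm(d$n, 0, noise_sd_mv)

  if (isTRUE(facilitated)) {
    hp <- signal::butter(4, 100 / (d$rate / 2), type = "high")
    x <- x + signal::filtfilt(hp, stats::rnorm(d$n, 0, facilitation_sd_mv))
  }

  out <- mep_ts(x, d$rate, anatomy = anatomy, side = side,
                excitation_pct = excitation_pct, visit_ref = visit_ref)
  attr(out, "true_latency_ms") <- latency_ms
  attr(out, "facilitated") <- isTRUE(facilitated)
  out
}

#' Generate a full synthetic MEP cohort with known ground truth
#'
#' Produces the visit table, recording set, EDSS history and a
#' ground-truth record. Each visit carries four limb recordings (APB and
#' AH, left and right). The two-year progression label of each visit is
#' drawn from a logistic model on the standardized values of the coupled
#' features, computed from the actually generated signals along the same
#' path the analysis pipeline uses (downsampling, artifact trimming,
#' left+right summation); the intercept is calibrated so the mean
#' progression probability equals the configured prevalence. EDSS
#' trajectories are then realized to be consistent with the drawn labels
#' under the two-threshold progression rule.
#'
#' @param config A [cohort_config()].
#' @return An `mep_cohort`: `visits`, `recordings` (metadata including
#'   the true generating parameters), `samples` (list of sample
#'   vectors), `edss_history`, and `ground_truth` (coupling, intercept,
#'   per-visit linear predictor, probability and label).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  np <- config$n_patients
  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(np)),
    age_years = round(pmin(pmax(stats::rnorm(np, 45, 12), 18), 85), 1),
    sex = sample(c("F", "M"), np, replace = TRUE, prob = c(301, 118) / 419),
    ms_type = sample(c("Unknown", "CIS", "PPMS", "RRMS", "SPMS"), np,
                     replace = TRUE, prob = c(138, 7, 12, 223, 45) / 419),
    edss0 = pmin(pmax(round(stats::rnorm(np, 3.0, 1.8) * 2) / 2, 0), 9),
    severity = stats::rnorm(np),
    stringsAsFactors = FALSE)

  limbs <- expand.grid(anatomy = c("APB", "AH"), side = c("L", "R"),
                       stringsAsFactors = FALSE)
  visits <- list(); rec_meta <- list(); samples <- list()
  vid <- 0L
  for (p in seq_len(np)) {
    nv <- sample(seq(config$visits_per_patient[1],
                     config$visits_per_patient[2]), 1L)
    date <- as.Date("2012-01-01") + sample.int(2000L, 1L)
    for (v in seq_len(nv)) {
      vid <- vid + 1L
      visit_id <- sprintf("V%05d", vid)
      z_v <- sqrt(0.7) * patients$severity[p] + sqrt(0.3) * stats::rnorm(1)
      dialect <- if (stats::runif(1) < config$machine_mix) "20kHz" else "19.2kHz"
      lat_ann <- c(APB_L = NA_real_, APB_R = NA_real_,
                   AH_L = NA_real_, AH_R = NA_real_)
      for (li in seq_len(nrow(limbs))) {
        an <- limbs$anatomy[li]; sd_ <- limbs$side[li]
        r <- config$latency_range_ms[[an]]
        lat <- mean(r) + 0.22 * diff(r) * (0.8 * z_v + 0.6 * stats::rnorm(1))
        lat <- min(max(lat, r[1] + 0.2), r[2] - 0.2)
        amp <- stats::runif(1, config$amplitude_range_mv[1],
                            config$amplitude_range_mv[2])
        tail_tau <- min(max(exp(log(12) + 0.40 *
                                  (0.8 * z_v + 0.6 * stats::rnorm(1))), 5), 28)
        phi <- min(max(0.55 + 0.18 * (0.8 * z_v + 0.6 * stats::rnorm(1)),
                       0.15, na.rm = TRUE), 0.92)
        fac <- stats::runif(1) < config$facilitation_rate
        exc <- sample(seq(45, 95, by = 5), 1L)
        ts <- generate_mep(lat, amp, facilitated = fac, dialect = dialect,
                           noise_sd_mv = config$noise_sd_mv,
                           tail_tau_ms = tail_tau, ar_phi = phi,
                           anatomy = an, side = sd_, excitation_pct = exc,
                           visit_ref = visit_id)
        rid <- sprintf("R%06d", length(samples) + 1L)
        samples[[rid]] <- ts$samples
        rec_meta[[length(rec_meta) + 1L]] <- data.frame(
          recording_id = rid, visit_id = visit_id,
          patient_id = patients$patient_id[p],
          anatomy = an, side = sd_, excitation_pct = exc,
          sampling_rate_hz = ts$sampling_rate_hz,
          n_samples = length(ts$samples),
          true_latency_ms = lat, true_facilitated = fac,
          true_tail_tau_ms = tail_tau, true_ar_phi = phi,
          stringsAsFactors = FALSE)
        lat_ann[paste(an, sd_, sep = "_")] <- lat + stats::rnorm(1, 0, 0.2)
      }
      visits[[vid]] <- data.frame(
        visit_id = visit_id, patient_id = patients$patient_id[p],
        date = date, age_years = patients$age_years[p],
        sex = patients$sex[p], ms_type = patients$ms_type[p],
        edss = patients$edss0[p],
        latency_apb_l_ms = lat_ann["APB_L"],
        latency_apb_r_ms = lat_ann["APB_R"],
        latency_ah_l_ms = lat_ann["AH_L"],
        latency_ah_r_ms = lat_ann["AH_R"],
        severity = z_v, stringsAsFactors = FALSE)
      date <- date + sample(120:400, 1L)
    }
  }
  visits <- do.call(rbind, visits)
  rownames(visits) <- NULL
  rec_meta <- do.call(rbind, rec_meta)

  cohort <- structure(
    list(visits = visits, recordings = rec_meta, samples = samples,
         edss_history = NULL, ground_truth = NULL, config = config),
    class = "mep_cohort")

  # ground-truth features, linear predictor and labels
  feat <- coupled_feature_values(cohort, names(config$coupling))
  lp <- rep(0, nrow(visits))
  zfeat <- feat
  if (length(config$coupling)) {
    zfeat <- scale(feat)
    lp <- as.numeric(zfeat %*% config$coupling[colnames(feat)])
    if (config$nonlinear_coupling && ncol(zfeat) >= 2L) {
      # the nonlinear regime is dominated by the interaction: the product
      # of two near-symmetric standardized features is linearly invisible
      # (its covariance with each factor is a vanishing odd moment), so a
      # linear classifier sees only the attenuated additive part
      lp <- 0.4 * lp + 2.0 * zfeat[, 1] * zfeat[, 2]
    }
  }
  b0 <- if (all(lp == 0)) {
    stats::qlogis(config$prevalence)
  } else {
    stats::uniroot(function(b) mean(stats::plogis(b + lp)) - config$prevalence,
                   c(-30, 30))$root
  }
  prob <- stats::plogis(b0 + lp)
  label <- stats::rbinom(nrow(visits), 1L, prob)

  # EDSS histories consistent with the drawn labels
  hist <- vector("list", nrow(visits))
  for (i in seq_len(nrow(visits))) {
    e0 <- visits$edss[i]
    if (label[i] == 1L) {
      inc <- if (e0 <= 5.5) 1.0 else 0.5
      if (stats::runif(1) < 0.25 && e0 + inc + 0.5 <= 10) inc <- inc + 0.5
      e1 <- e0 + inc
    } else {
      choices <- if (e0 > 5.5) c(-0.5, 0) else c(-0.5, 0, 0.5)
      choices <- choices[e0 + choices >= 0]
      e1 <- e0 + sample(choices, 1L)
    }
    rows <- data.frame(patient_id = visits$patient_id[i],
                       date = visits$date[i], edss = e0,
                       stringsAsFactors = FALSE)
    if (stats::runif(1) >= config$dropout_rate) {
      t1_date <- visits$date[i] + round(2 * DAYS_PER_YEAR +
                                          stats::runif(1, -36.5, 36.5))
      rows <- rbind(rows, data.frame(patient_id = visits$patient_id[i],
                                     date = t1_date, edss = e1,
                                     stringsAsFactors = FALSE))
    }
    hist[[i]] <- rows
  }
  edss_history <- do.call(rbind, hist)
  edss_history <- edss_history[order(edss_history$patient_id,
                                     edss_history$date), ]
  rownames(edss_history) <- NULL

  cohort$edss_history <- edss_history
  cohort$ground_truth <- structure(
    list(coupling = config$coupling,
         nonlinear_coupling = config$nonlinear_coupling,
         designated = names(config$coupling),
         intercept = b0,
         feature_values = feat,
         linear_predictor = stats::setNames(lp, visits$visit_id),
         probability = stats::setNames(prob, visits$visit_id),
         label = stats::setNames(label, visits$visit_id)),
    class = "mep_ground_truth")
  cohort
}

# Values of the coupled features per visit, in the representation the
# analysis pipeline works with: "latency" is the mean true latency over
# the four limbs; "<anatomy>_<feature>" is the left+right sum of the
# robust-sigmoid-normalized catalog feature (Eq.-style normalization with
# median/iqr estimated over that anatomy's recordings of the whole
# cohort), computed on the standard-rate trimmed traces. Defining the
# ground truth in the pipeline's own feature space keeps the Bayes
# ceiling attainable by a correctly specified classifier.
coupled_feature_values <- function(cohort, names_wanted) {
  visits <- cohort$visits
  if (length(names_wanted) == 0L) {
    return(matrix(numeric(0), nrow(visits), 0))
  }
  rec <- cohort$recordings
  out <- matrix(NA_real_, nrow(visits), length(names_wanted),
                dimnames = list(visits$visit_id, names_wanted))
  if ("latency" %in% names_wanted) {
    out[, "latency"] <- tapply(rec$true_latency_ms, rec$visit_id,
                               mean)[visits$visit_id]
  }
  catalog_wanted <- setdiff(names_wanted, "latency")
  if (length(catalog_wanted) == 0L) return(out)

  trimmed_cache <- new.env(parent = emptyenv())
  get_trimmed <- function(rid) {
    if (!is.null(trimmed_cache[[rid]])) return(trimmed_cache[[rid]])
    v <- trim_artifact(resample_to_standard(cohort_recording(cohort, rid)))
    trimmed_cache[[rid]] <- v
    v
  }
  for (nm in catalog_wanted) {
    an <- toupper(sub("_.*", "", nm))
    feat <- sub("^[^_]+_", "", nm)
    idx <- which(rec$anatomy == an)
    raw <- vapply(rec$recording_id[idx], function(rid) {
      compute_catalog_feature(get_trimmed(rid), feat)
    }, numeric(1))
    med <- stats::median(raw)
    iqr <- diff(stats::quantile(raw, c(0.25, 0.75), names = FALSE, type = 7))
    norm <- stats::plogis((raw - med) / (iqr / 1.35))
    out[, nm] <- tapply(norm, rec$visit_id[idx], sum)[visits$visit_id]
  }
  out
}

compute_catalog_feature <- function(x, feat) {
  switch(feat,
         sw_disp_w50_s25 = sliding_window_dispersion(x, 1 / 2, 1 / 4),
         sw_disp_w25_s12 = sliding_window_dispersion(x, 1 / 4, 1 / 8),
         sw_disp_w25_s25 = sliding_window_dispersion(x, 1 / 4, 1 / 4),
         sw_disp_w50_s12 = sliding_window_dispersion(x, 1 / 2, 1 / 8),
         ar2_resid_ac1 = ar_residual_autocorr(x),
         catalog_features(x)[[feat]])
}

#' @export
print.mep_cohort <- function(x, ...) {
  cat(sprintf("<mep_cohort> %d patients, %d visits, %d recordings\n",
              length(unique(x$visits$patient_id)), nrow(x$visits),
              nrow(x$recordings)))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  ground truth: prevalence %.3f, coupling on %s\n",
                mean(x$ground_truth$label),
                paste(x$ground_truth$designated, collapse = ", ")))
  }
  invisible(x)
}

#' Monte-Carlo estimate of the Bayes AUC of the ground-truth model
#'
#' The true linear predictor of the generator is the best possible score
#' for the progression label it generates; its AUC against labels drawn
#' from the generative model is the ceiling for any classifier on this
#' cohort. The estimate redraws the cohort's labels `n_mc` times and
#' averages the AUC of the linear predictor against each draw.
#'
#' @param ground_truth The `ground_truth` element of a generated cohort.
#' @param n_mc Number of Monte-Carlo label redraws (>= 100).
#' @param seed RNG seed.
#' @return Scalar estimate in `[0.5, 1]` with a `se` attribute (standard
#'   error over redraws).
#' @export
bayes_auc_estimate <- function(ground_truth, n_mc = 200L, seed = 1L) {
  stopifnot(inherits(ground_truth, "mep_ground_truth"))
  if (n_mc < 100L) stop("'n_mc' must be at least 100", call. = FALSE)
  lp <- ground_truth$linear_predictor
  prob <- ground_truth$probability
  aucs <- with_seed(seed, {
    vapply(seq_len(n_mc), function(r) {
      yy <- stats::rbinom(length(prob), 1L, prob)
      if (length(unique(yy)) < 2L) return(NA_real_)
      auc(yy, lp)
    }, numeric(1))
  })
  aucs <- aucs[!is.na(aucs)]
  structure(max(0.5, mean(aucs)), se = stats::sd(aucs) / sqrt(length(aucs)))
}
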