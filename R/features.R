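# Time-series feature catalog, robust sigmoid normalization and
# left-right symmetrization.

#' Sliding-window dispersion of a time series
#'
#' Slides a window of `window_frac` of the series length across the series
#' in steps of `step_frac` of the length, computes each window's mean, and
#' returns the (population) standard deviation of these means divided by
#' the (population) standard deviation of the whole series. At the default
#' half-length window and quarter-length step exactly three windows are
#' considered. In practice the feature characterizes how fast the trace
#' returns to an average of zero after the response.
#'
#' @param x Numeric vector (a trimmed recording), length >= 8.
#' @param window_frac Window length as a fraction of `length(x)`.
#' @param step_frac Step as a fraction of `length(x)`.
#' @return A non-negative scalar; `NaN` when the series is constant.
#' @export
sliding_window_dispersion <- function(x, window_frac = 1 / 2,
                                      step_frac = 1 / 4) {
  n <- length(x)
  if (n < 8L) stop("series too short (need length >= 8)", call. = FALSE)
  wl <- floor(n * window_frac)
  step <- max(1L, floor(n * step_frac))
  starts <- seq(0L, n - wl, by = step)  # 0-based offsets
  cs <- c(0, cumsum(x))
  means <- (cs[starts + wl + 1L] - cs[starts + 1L]) / wl
  s_all <- pop_sd(x)
  if (s_all == 0) return(NaN)
  pop_sd(means) / s_all
}

#' Autocorrelation of one-step-ahead AR residuals on uniform subsets
#'
#' Fits an autoregressive model of order `order` (Yule-Walker) to the
#' whole series and forms the one-step-ahead prediction residuals, where
#' each prediction uses the true preceding values. From the residual
#' series, `n_subsets` contiguous segments of length
#' `round(subset_frac * length(x))` with uniformly spaced starts are
#' taken; the lag-1 autocorrelation of each segment is computed, and the
#' absolute value of the mean of these autocorrelations is returned. On a
#' 1920-sample input each segment holds 192 residuals. For a correctly
#' specified AR process the residuals are white and the value is near 0.
#'
#' @param x Numeric vector.
#' @param order AR order (default 2).
#' @param n_subsets Number of segments (default 25).
#' @param subset_frac Segment length as a fraction of `length(x)`.
#' @return Scalar in `[0, 1]`; `NaN` if the AR fit fails.
#' @export
ar_residual_autocorr <- function(x, order = 2L, n_subsets = 25L,
                                 subset_frac = 0.1) {
  n <- length(x)
  len <- round(subset_frac * n)
  if (len < 2L || n < order + len + 1L) {
    stop("series too short for AR subsets", call. = FALSE)
  }
  fit <- tryCatch(
    stats::ar(x, aic = FALSE, order.max = order, method = "yule-walker",
              demean = TRUE),
    error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) < order) return(NaN)
  a <- fit$ar
  m <- fit$x.mean
  xc <- x - m
  pred <- rep(0, n - order)
  for (k in seq_len(order)) {
    pred <- pred + a[k] * xc[(order - k + 1L):(n - k)]
  }
  res <- xc[(order + 1L):n] - pred          # length n - order
  nr <- length(res)
  starts <- round(seq(1L, nr - len + 1L, length.out = n_subsets))
  ac1 <- vapply(starts, function(s) {
    seg <- res[s:(s + len - 1L)]
    seg <- seg - mean(seg)
    c0 <- sum(seg^2)
    if (c0 == 0) return(0)
    sum(seg[-len] * seg[-1L]) / c0
  }, numeric(1))
  abs(mean(ac1))
}

catalog_feature_names <- function() {
  c("sw_disp_w50_s25", "sw_disp_w25_s12", "sw_disp_w25_s25",
    "sw_disp_w50_s12", "ar2_resid_ac1",
    paste0("bp_frac_", 1:5), "spec_centroid",
    paste0("acf_lag", c(1, 2, 3, 5, 10, 20, 50, 100)),
    "pacf_lag2", "pacf_lag3", "acf_first_min_lag", "acf_sq_lag1",
    "sd", "skewness", "kurtosis", "argmax_abs_frac", "surprise_hist20",
    "zero_cross_rate", "hjorth_mobility", "hjorth_complexity",
    "spec_entropy", "spec_rolloff85", "band_ratio_hl", "trend_r",
    "quantile_ratio", "outlier_frac_2sd", "longest_above_mean_frac",
    "swin_mean_range_w25_s12", "diff2_rms_ratio")
}

#' Compute the full feature catalog for one trimmed recording
#'
#' A fixed-order named vector of time-series features spanning the main
#' families of a comparative time-series analysis library: sliding-window
#' dispersion at window fractions 1/4 and 1/2 crossed with step fractions
#' 1/8 and 1/4; the AR(2) residual autocorrelation feature; periodogram
#' band-power fractions in 5 logarithmic bands, spectral centroid,
#' entropy, 85% rolloff and a high/low band-power ratio (all on
#' normalized frequency); autocorrelations at lags 1-100, partial
#' autocorrelations, the lag of the first local acf minimum, and the
#' lag-1 autocorrelation of the squared series; population standard
#' deviation, skewness, excess kurtosis, a quantile-spread ratio, the
#' outlier fraction beyond 2 SD and the linear-trend correlation; the
#' relative time index of the absolute maximum, zero-crossing rate,
#' longest run above the mean, Hjorth mobility and complexity, a
#' second-difference roughness ratio, the range of sliding-window means;
#' and a surprise score (the mean negative log probability of second-half
#' samples under a 20-bin histogram fit on the first half, with add-one
#' smoothing). Degenerate inputs yield `NaN` entries rather than errors.
#'
#' @param x Numeric vector, a trimmed (post-artifact) recording.
#' @return Named numeric vector; names and order are fixed across inputs.
#' @export
catalog_features <- function(x) {
  n <- length(x)
  out <- stats::setNames(rep(NaN, length(catalog_feature_names())),
                         catalog_feature_names())
  s <- pop_sd(x)
  sw <- function(w, st) tryCatch(sliding_window_dispersion(x, w, st),
                                 error = function(e) NaN)
  out["sw_disp_w50_s25"] <- sw(1 / 2, 1 / 4)
  out["sw_disp_w25_s12"] <- sw(1 / 4, 1 / 8)
  out["sw_disp_w25_s25"] <- sw(1 / 4, 1 / 4)
  out["sw_disp_w50_s12"] <- sw(1 / 2, 1 / 8)
  out["ar2_resid_ac1"] <- tryCatch(ar_residual_autocorr(x),
                                   error = function(e) NaN)

  # spectral features from one periodogram (normalized frequency)
  if (s > 0) {
    xf <- stats::fft(x - mean(x))
    half <- 2:(floor(n / 2) + 1L)
    p <- Mod(xf[half])^2
    f <- (half - 1) / n                     # cycles per sample, (0, 0.5]
    tot <- sum(p)
    breaks <- exp(seq(log(0.002), log(0.5), length.out = 6L))
    breaks[1] <- 0                          # lowest band absorbs everything below
    band <- cut(f, breaks, labels = FALSE, include.lowest = TRUE)
    for (b in 1:5) {
      out[paste0("bp_frac_", b)] <- sum(p[band == b]) / tot
    }
    out["spec_centroid"] <- sum(f * p) / tot

    out["spec_entropy"] <- {
      pp <- p / tot
      -sum(pp[pp > 0] * log(pp[pp > 0])) / log(length(p))
    }
    out["spec_rolloff85"] <- f[which(cumsum(p) >= 0.85 * tot)[1L]]
    lo <- sum(p[f < 0.05])
    out["band_ratio_hl"] <- if (lo > 0) sum(p[f >= 0.05]) / lo else NaN

    ac <- stats::acf(x, lag.max = 100L, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    for (lg in c(1, 2, 3, 5, 10, 20, 50, 100)) {
      out[paste0("acf_lag", lg)] <- ac[lg + 1L]
    }
    pac <- tryCatch(stats::pacf(x, lag.max = 3L, plot = FALSE)$acf[, 1, 1],
                    error = function(e) rep(NaN, 3L))
    out["pacf_lag2"] <- pac[2L]
    out["pacf_lag3"] <- pac[3L]
    dmin <- which(diff(ac) > 0)  # first rise after a fall = local minimum
    out["acf_first_min_lag"] <- if (length(dmin)) (dmin[1L]) / 100 else 1
    x2 <- (x - mean(x))^2
    out["acf_sq_lag1"] <- if (pop_sd(x2) > 0) {
      stats::acf(x2, lag.max = 1L, plot = FALSE)$acf[2L, 1, 1]
    } else NaN

    z <- (x - mean(x)) / s
    out["skewness"] <- mean(z^3)
    out["kurtosis"] <- mean(z^4) - 3
    out["outlier_frac_2sd"] <- mean(abs(z) > 2)
    out["trend_r"] <- stats::cor(x, seq_len(n))
    q <- stats::quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
    out["quantile_ratio"] <- if (q[3] > q[2]) (q[4] - q[1]) / (q[3] - q[2]) else NaN
    sgn <- sign(x - mean(x))
    out["zero_cross_rate"] <- mean(sgn[-1L] != sgn[-n])
    runs <- rle(sgn > 0)
    above <- runs$lengths[runs$values]
    out["longest_above_mean_frac"] <- if (length(above)) max(above) / n else 0
    d1 <- diff(x); d2 <- diff(d1)
    mob <- stats::sd(d1) / s
    out["hjorth_mobility"] <- mob
    out["hjorth_complexity"] <- if (stats::sd(d1) > 0) {
      (stats::sd(d2) / stats::sd(d1)) / mob
    } else NaN
    out["diff2_rms_ratio"] <- sqrt(mean(d2^2)) / s
    out["swin_mean_range_w25_s12"] <- {
      wl <- floor(n / 4); st <- floor(n / 8)
      starts <- seq(0L, n - wl, by = st)
      cs <- c(0, cumsum(x))
      mns <- (cs[starts + wl + 1L] - cs[starts + 1L]) / wl
      (max(mns) - min(mns)) / s
    }
  }
  out["sd"] <- if (s > 0) s else NaN
  out["argmax_abs_frac"] <- (which.max(abs(x)) - 1L) / n

  # surprise: histogram memory from the first half, scored on the second
  h1 <- x[seq_len(floor(n / 2))]
  h2 <- x[(floor(n / 2) + 1L):n]
  rng <- range(h1)
  if (diff(rng) > 0) {
    nb <- 20L
    brk <- seq(rng[1], rng[2], length.out = nb + 1L)
    cnt <- tabulate(pmin(pmax(findInterval(h1, brk, all.inside = TRUE), 1L), nb),
                    nbins = nb)
    prob <- (cnt + 1) / (length(h1) + nb)   # add-one smoothing
    bin2 <- pmin(pmax(findInterval(h2, brk, all.inside = TRUE), 1L), nb)
    out["surprise_hist20"] <- mean(-log(prob[bin2]))
  }
  out
}

#' Build the raw feature matrix of a preprocessed cohort
#'
#' Trims the stimulus artifact from every selected recording and computes
#' the feature catalog, producing one row per (visit, anatomy, side).
#'
#' @param cohort A preprocessed [mep_cohort] (see [preprocess_cohort()]).
#' @param n_trim Leading samples to discard (default 70).
#' @return A `feature_matrix` object (values, row keys, discarded-column
#'   log).
#' @export
extract_features <- function(cohort, n_trim = ARTIFACT_SAMPLES) {
  rec <- cohort$recordings
  vals <- matrix(NA_real_, nrow(rec), length(catalog_feature_names()),
                 dimnames = list(NULL, catalog_feature_names()))
  for (i in seq_len(nrow(rec))) {
    x <- trim_artifact(cohort$samples[[rec$recording_id[i]]], n_trim)
    vals[i, ] <- catalog_features(x)
  }
  feature_matrix(vals,
                 keys = data.frame(visit_id = rec$visit_id,
                                   anatomy = rec$anatomy,
                                   side = rec$side,
                                   stringsAsFactors = FALSE))
}

#' Feature matrix container
#'
#' Couples a numeric feature table with its row keys (visit, anatomy and
#' optionally side) and a log of discarded columns.
#'
#' @param values Numeric matrix, columns named by feature.
#' @param keys Data frame with one row per matrix row.
#' @param discarded Data frame logging removed columns and reasons.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, keys,
                           discarded = data.frame(column = character(),
                                                  reason = character(),
                                                  stringsAsFactors = FALSE)) {
  stopifnot(is.matrix(values), nrow(values) == nrow(keys))
  structure(list(values = values, keys = keys, discarded = discarded),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d rows x %d features (%d discarded)\n",
              nrow(x$values), ncol(x$values), nrow(x$discarded)))
  invisible(x)
}

#' Robust sigmoid normalization of feature columns
#'
#' Maps each column through
#' `x -> 1 / (1 + exp(-(x - median) / (iqr / 1.35)))`, with `iqr` the
#' interquartile range (linearly interpolated quantiles). Because the
#' median and iqr are used the transform is robust to outliers, and it is
#' invariant to affine rescaling of a column. Columns containing
#' non-finite raw values, and columns whose transform produces
#' non-finite values (e.g. constant columns with zero iqr), are discarded
#' and logged.
#'
#' @param m A `feature_matrix` of raw features.
#' @return A `feature_matrix` with all retained values in (0, 1).
#' @export
robust_sigmoid_normalize <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  vals <- m$values
  keep <- logical(ncol(vals))
  disc <- m$discarded
  out <- vals
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    if (any(!is.finite(x))) {
      disc <- rbind(disc, data.frame(column = colnames(vals)[j],
                                     reason = "raw column contains NaN/NA",
                                     stringsAsFactors = FALSE))
      next
    }
    med <- stats::median(x)
    iqr <- diff(stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7))
    y <- stats::plogis((x - med) / (iqr / 1.35))
    if (iqr == 0 || any(!is.finite(y))) {
      disc <- rbind(disc, data.frame(column = colnames(vals)[j],
                                     reason = "normalization produced NaN (zero iqr)",
                                     stringsAsFactors = FALSE))
      next
    }
    eps <- .Machine$double.eps
    out[, j] <- pmin(pmax(y, eps), 1 - eps)
    keep[j] <- TRUE
  }
  feature_matrix(out[, keep, drop = FALSE], m$keys, disc)
}

#' Sum features over the left and right side
#'
#' Exploits the left-right symmetry of the limb measurements by summing
#' the (normalized) features of both sides, halving the number of rows to
#' one per (visit, anatomy).
#'
#' @param m A normalized `feature_matrix` keyed by (visit, anatomy, side).
#' @return A `feature_matrix` keyed by (visit, anatomy), values in (0, 2).
#' @export
sum_left_right <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  k <- m$keys
  if (is.null(k$side)) stop("feature matrix is not keyed by side", call. = FALSE)
  key <- paste(k$visit_id, k$anatomy, sep = "|")
  groups <- split(seq_len(nrow(k)), key)
  bad <- names(groups)[vapply(groups, function(idx) {
    !setequal(k$side[idx], c("L", "R"))
  }, logical(1))]
  if (length(bad)) {
    stop(sprintf("missing side for %d (visit, anatomy) pairs, e.g. %s",
                 length(bad), bad[1]), call. = FALSE)
  }
  ord <- names(groups)
  vals <- do.call(rbind, lapply(groups, function(idx) {
    colSums(m$values[idx, , drop = FALSE])
  }))
  rownames(vals) <- NULL
  parts <- do.call(rbind, strsplit(ord, "|", fixed = TRUE))
  feature_matrix(vals,
                 keys = data.frame(visit_id = parts[, 1], anatomy = parts[, 2],
                                   stringsAsFactors = FALSE),
                 discarded = m$discarded)
}
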