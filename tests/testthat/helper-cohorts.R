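# Shared fixtures, generated once per test run and memoized.

memo <- local({
  cache <- new.env(parent = emptyenv())
  function(key, expr) {
    if (is.null(cache[[key]])) cache[[key]] <- force(expr)
    cache[[key]]
  }
})

# Small cohort with default coupling, for structural and round-trip tests.
small_cohort <- function() {
  memo("small", generate_cohort(cohort_config(n_patients = 25L, seed = 101L)))
}

small_prepared <- function() {
  memo("small_prep", prepare_cohort(small_cohort()))
}

# Zero-coupling cohort: labels are independent Bernoulli draws.
null_cohort <- function() {
  memo("null", generate_cohort(cohort_config(n_patients = 60L,
                                             coupling = NULL, seed = 202L)))
}

null_prepared <- function() {
  memo("null_prep", prepare_cohort(null_cohort()))
}

# The parameter-recovery cohort: ~2000 visits, label coupled to latency and
# the two named time-series features.
recovery_cohort <- function() {
  memo("recovery", generate_cohort(cohort_config(n_patients = 340L,
                                                 seed = 20260901L)))
}

recovery_prepared <- function() {
  memo("recovery_prep", prepare_cohort(recovery_cohort()))
}

# Nonlinear-coupling cohort for the classifier comparison.
nonlinear_cohort <- function() {
  memo("nonlinear",
       generate_cohort(cohort_config(n_patients = 130L,
                                     nonlinear_coupling = TRUE, seed = 303L)))
}

nonlinear_prepared <- function() {
  memo("nonlinear_prep", prepare_cohort(nonlinear_cohort()))
}

# --- independent oracles -------------------------------------------------

# Pairwise-counting AUC: every positive-negative pair, ties one half.
auc_bruteforce <- function(y, s) {
  xp <- s[y == 1]
  xn <- s[y == 0]
  tot <- 0
  for (a in xp) for (b in xn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xp) * length(xn))
}

# DeLong variance of the AUC difference by direct placement-value
# summation with scalar loops.
delong_var_bruteforce <- function(y, sa, sb) {
  ip <- which(y == 1); inn <- which(y == 0)
  m <- length(ip); n <- length(inn)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- matrix(0, m, 2); v01 <- matrix(0, n, 2)
  for (k in 1:2) {
    s <- if (k == 1) sa else sb
    for (i in seq_len(m)) {
      acc <- 0
      for (j in seq_len(n)) acc <- acc + psi(s[ip[i]], s[inn[j]])
      v10[i, k] <- acc / n
    }
    for (j in seq_len(n)) {
      acc <- 0
      for (i in seq_len(m)) acc <- acc + psi(s[ip[i]], s[inn[j]])
      v01[j, k] <- acc / m
    }
  }
  cv <- function(a, b) sum((a - mean(a)) * (b - mean(b))) / (length(a) - 1)
  (cv(v10[, 1], v10[, 1]) + cv(v10[, 2], v10[, 2]) - 2 * cv(v10[, 1], v10[, 2])) / m +
    (cv(v01[, 1], v01[, 1]) + cv(v01[, 2], v01[, 2]) - 2 * cv(v01[, 1], v01[, 2])) / n
}

# Direct-enumeration sliding-window dispersion: means of exactly the
# windows at offsets {0, floor(N/4), 2*floor(N/4)}, population SDs.
sliding_dispersion_oracle <- function(x) {
  n <- length(x)
  wl <- floor(n / 2)
  offs <- c(0, floor(n / 4), 2 * floor(n / 4))
  means <- vapply(offs, function(o) mean(x[(o + 1):(o + wl)]), numeric(1))
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  psd(means) / psd(x)
}

# Direct AR-residual oracle: Yule-Walker AR fit, full one-step-ahead
# residual series, then exactly n_subsets windows of length round(0.1 N).
ar_residual_oracle <- function(x, order = 2, n_subsets = 25) {
  n <- length(x)
  len <- round(0.1 * n)
  fit <- stats::ar(x, aic = FALSE, order.max = order, method = "yule-walker")
  res <- numeric(n - order)
  for (t in (order + 1):n) {
    pred <- fit$x.mean + sum(fit$ar * (x[t - seq_len(order)] - fit$x.mean))
    res[t - order] <- x[t] - pred
  }
  starts <- round(seq(1, length(res) - len + 1, length.out = n_subsets))
  ac <- numeric(n_subsets)
  for (i in seq_len(n_subsets)) {
    seg <- res[starts[i]:(starts[i] + len - 1)]
    stopifnot(length(seg) == len)
    seg <- seg - mean(seg)
    ac[i] <- sum(seg[-len] * seg[-1]) / sum(seg^2)
  }
  list(value = abs(mean(ac)), n_windows = n_subsets, window_len = len)
}
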