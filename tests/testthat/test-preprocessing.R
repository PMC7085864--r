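test_that("peak_to_peak is max minus min", {
  expect_equal(peak_to_peak(c(1, -1, 0.5)), 2.0)
  expect_equal(peak_to_peak(rep(3.2, 100)), 0)
  a <- 0.7
  dense_sine <- a * sin(seq(0, 20 * pi, length.out = 5000))
  expect_lt(abs(peak_to_peak(dense_sine) - 2 * a), 1e-4)
  expect_error(peak_to_peak(numeric()), "empty")
})

test_that("the 20 kHz dialect downsamples to 1920 samples", {
  t20 <- (0:1999) / 20000
  ts <- mep_ts(sin(2 * pi * 200 * t20), 20000)
  out <- resample_to_standard(ts)
  expect_length(out$samples, 1920L)
  expect_equal(out$sampling_rate_hz, 19200)
  # monotone time mapping keeps low-frequency content: 200 Hz amplitude
  # preserved within 1%
  expect_lt(abs(max(out$samples) - 1) , 0.01)
  # values stay inside the input envelope
  expect_gte(min(out$samples), min(ts$samples))
  expect_lte(max(out$samples), max(ts$samples))

  # constant series stays constant
  cst <- resample_to_standard(mep_ts(rep(2.5, 2000), 20000))
  expect_equal(cst$samples, rep(2.5, 1920))

  # standard recordings pass through unchanged
  std <- mep_ts(rnorm(1920), 19200)
  expect_identical(resample_to_standard(std), std)

  expect_error(resample_to_standard(mep_ts(rnorm(1000), 10000)),
               "unsupported dialect")
})

test_that("facilitation detection separates contracted from quiescent", {
  set.seed(21)
  fac <- generate_mep(25, 0.8, facilitated = TRUE)
  quiet <- generate_mep(25, 0.8, facilitated = FALSE)
  expect_true(detect_facilitation(fac))
  expect_false(detect_facilitation(quiet))
  expect_false(detect_facilitation(fac, power_threshold = Inf))
  expect_error(detect_facilitation(fac, power_threshold = -1), "positive")
})

test_that("the calibrated threshold flags >=95% facilitated, <=5% quiescent", {
  set.seed(22)
  n_each <- 250L
  flags <- matrix(NA, n_each, 2)
  for (i in seq_len(n_each)) {
    lat <- runif(1, 19, 45)
    amp <- runif(1, 0.2, 1.0)
    tau <- runif(1, 5, 28)
    phi <- runif(1, 0.15, 0.92)
    flags[i, 1] <- detect_facilitation(
      generate_mep(lat, amp, facilitated = TRUE, tail_tau_ms = tau,
                   ar_phi = phi))
    flags[i, 2] <- detect_facilitation(
      generate_mep(lat, amp, facilitated = FALSE, tail_tau_ms = tau,
                   ar_phi = phi))
  }
  expect_gte(mean(flags[, 1]), 0.95)
  expect_lte(mean(flags[, 2]), 0.05)
})

test_that("maximum-amplitude selection picks the largest response", {
  mk <- function(p2p, exc) mep_ts(c(-p2p / 2, p2p / 2, rep(0, 100)), 19200,
                                  excitation_pct = exc)
  recs <- list(mk(0.4, 55), mk(0.9, 65), mk(0.7, 75))
  expect_equal(peak_to_peak(select_max_amplitude(recs)), 0.9)
  # invariant to input order
  expect_equal(peak_to_peak(select_max_amplitude(rev(recs))), 0.9)
  # single recording returns itself
  expect_identical(select_max_amplitude(recs[2]), recs[[2]])
  # exact tie: lowest excitation wins
  tie <- list(mk(0.5, 80), mk(0.5, 60))
  expect_equal(select_max_amplitude(tie)$excitation_pct, 60)
  expect_error(select_max_amplitude(list()), "no recordings")
})

test_that("artifact trimming drops exactly the first 70 samples", {
  x <- rnorm(1920)
  out <- trim_artifact(x)
  expect_length(out, 1850L)
  expect_identical(out, x[71:1920])
  expect_equal(trim_artifact(rep(4, 1920)), rep(4, 1850))
  expect_error(trim_artifact(rnorm(50)), "trim")
})

test_that("visit filters keep only complete 100 ms visits", {
  rec <- data.frame(
    visit_id = c(rep("V1", 4), rep("V2", 3), rep("V3", 4)),
    anatomy = c("APB", "APB", "AH", "AH", "APB", "APB", "AH",
                "APB", "APB", "AH", "AH"),
    side = c("L", "R", "L", "R", "L", "R", "L", "L", "R", "L", "R"),
    n_samples = c(rep(1920L, 7), 1920L, 1920L, 960L, 1920L),
    sampling_rate_hz = rep(19200, 11))
  visits <- data.frame(visit_id = c("V1", "V2", "V3"))
  kept <- filter_visits(visits, rec)
  # V2 misses a limb; V3's AH L lasts 50 ms, so the limb (and visit) drops
  expect_equal(kept$visit_id, "V1")
})

test_that("cohort preprocessing is idempotent and auditable", {
  co <- small_cohort()
  once <- preprocess_cohort(co)
  twice <- preprocess_cohort(once)
  expect_identical(once$visits, twice$visits)
  expect_identical(once$samples, twice$samples)
  log <- attr(once, "filter_log")
  expect_true(all(c("stage", "rows_before", "rows_after", "reason")
                  %in% names(log)))
  expect_true(all(log$rows_after <= log$rows_before))
  # every surviving visit has its 4 limbs, at the standard dialect
  expect_true(all(once$recordings$n_samples == 1920L))
  expect_true(all(table(once$recordings$visit_id) == 4L))
})
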