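test_that("generated recordings have the documented signal geometry", {
  set.seed(1)
  ts <- generate_mep(25, 1.0, dialect = "19.2kHz")
  expect_s3_class(ts, "mep_ts")
  expect_length(ts$samples, 1920L)
  expect_equal(ts$sampling_rate_hz, 19200)

  ts20 <- generate_mep(25, 1.0, dialect = "20kHz")
  expect_length(ts20$samples, 2000L)
  expect_equal(ts20$sampling_rate_hz, 20000)

  # realized peak-to-peak tracks the requested response amplitude
  expect_lt(abs(peak_to_peak(ts) - 1.0), 0.1)

  # pre-latency segment is quiet: between 5 ms and 24 ms (latency 25 ms)
  # only baseline noise remains (white + colored background)
  seg <- ts$samples[round(0.005 * 19200):round(0.024 * 19200)]
  expect_lt(sd(seg), 2 * 0.01 + 0.012)
  expect_lt(max(abs(seg)), 6 * 0.01)
})

test_that("facilitated recordings carry pre-latency power", {
  set.seed(7)
  fac <- generate_mep(25, 1.0, facilitated = TRUE)
  set.seed(7)
  quiet <- generate_mep(25, 1.0, facilitated = FALSE)
  pw <- function(x) mean((x - mean(x))^2)
  seg <- function(ts) ts$samples[71:326]
  expect_gte(pw(seg(fac)) / pw(seg(quiet)), 10)
})

test_that("recording generation is deterministic and validates inputs", {
  set.seed(11)
  a <- generate_mep(30, 0.5)
  set.seed(11)
  b <- generate_mep(30, 0.5)
  expect_identical(a$samples, b$samples)

  expect_error(generate_mep(2, 1.0), "latency")     # inside artifact window
  expect_error(generate_mep(99, 1.0), "latency")    # beyond the window
  expect_error(generate_mep(25, -1), "amplitude")
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(prevalence = 1.2), "prevalence")
  expect_error(cohort_config(latency_range_ms = list(APB = c(10, 30),
                                                     AH = c(30, 45))),
               "17 ms")
})

test_that("generated cohorts are referentially intact with 4 limbs per visit", {
  co <- small_cohort()
  expect_true(all(co$recordings$visit_id %in% co$visits$visit_id))
  expect_true(all(co$visits$patient_id %in% co$recordings$patient_id))
  expect_true(all(co$edss_history$patient_id %in% co$visits$patient_id))
  limb_counts <- table(co$recordings$visit_id)
  expect_true(all(limb_counts == 4L))
  limbs <- with(co$recordings, tapply(paste(anatomy, side), visit_id,
                                      function(v) length(unique(v))))
  expect_true(all(limbs == 4L))
  expect_setequal(names(co$samples), co$recordings$recording_id)
  # exactly one ground-truth record per visit
  expect_setequal(names(co$ground_truth$label), co$visits$visit_id)
})

test_that("cohort generation is reproducible from its seed", {
  cfg <- cohort_config(n_patients = 4L, seed = 55L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$visits, b$visits)
  expect_identical(a$samples, b$samples)
  expect_identical(a$edss_history, b$edss_history)
  expect_identical(a$ground_truth$label, b$ground_truth$label)
})

test_that("realized prevalence stays in the binomial band around 11%", {
  co <- recovery_cohort()
  lab <- co$ground_truth$label
  n <- length(lab)
  band <- qnorm(0.995) * sqrt(0.11 * 0.89 / n)
  expect_gt(mean(lab), 0.11 - band)
  expect_lt(mean(lab), 0.11 + band)
})

test_that("zero coupling yields labels unrelated to any feature", {
  co <- null_cohort()
  gt <- co$ground_truth
  expect_true(all(gt$linear_predictor == 0))
  expect_equal(unname(gt$probability), rep(0.11, nrow(co$visits)))
  # point-biserial association of annotated latency with the label ~ 0
  r <- cor(co$visits$latency_apb_l_ms, gt$label[co$visits$visit_id])
  expect_lt(abs(r), 3 / sqrt(nrow(co$visits)))
})

test_that("Bayes AUC estimate behaves as an oracle ceiling", {
  expect_error(bayes_auc_estimate(null_cohort()$ground_truth, n_mc = 50),
               "n_mc")
  # no signal: exactly 1/2 (constant linear predictor, all ties)
  b0 <- bayes_auc_estimate(null_cohort()$ground_truth, 100, seed = 1)
  expect_equal(as.numeric(b0), 0.5)

  # informative cohort sits strictly above 1/2, with a small MC error
  gt <- small_cohort()$ground_truth
  b1 <- bayes_auc_estimate(gt, 200, seed = 1)
  expect_gt(b1, 0.6)
  expect_lt(attr(b1, "se"), 0.02)

  # doubling the coupling never decreases the ceiling beyond MC error
  gt2 <- gt
  gt2$linear_predictor <- 2 * gt$linear_predictor
  gt2$probability <- plogis(gt$intercept + gt2$linear_predictor)
  b2 <- bayes_auc_estimate(gt2, 200, seed = 2)
  expect_gte(b2, b1 - 3 * (attr(b1, "se") + attr(b2, "se")))

  # extreme coupling drives the ceiling toward 1
  gt3 <- gt
  gt3$linear_predictor <- 50 * gt$linear_predictor
  gt3$probability <- plogis(gt3$linear_predictor)
  expect_gt(bayes_auc_estimate(gt3, 100, seed = 3), 0.95)
})
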