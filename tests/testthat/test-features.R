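test_that("sliding-window dispersion matches direct enumeration", {
  # 8-point worked example: window means {0, 0.5, 1}, value sqrt(1/6)/0.5
  x <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_equal(sliding_window_dispersion(x), sqrt(1 / 6) / 0.5,
               tolerance = 1e-12)
  expect_equal(sliding_window_dispersion(x), 0.8164966, tolerance = 1e-6)

  set.seed(5)
  for (n in c(64, 500, 1850, 1920)) {
    z <- cumsum(rnorm(n))
    expect_equal(sliding_window_dispersion(z), sliding_dispersion_oracle(z),
                 tolerance = 1e-12)
  }

  expect_true(is.nan(sliding_window_dispersion(rep(2, 100))))
  expect_error(sliding_window_dispersion(1:4), "short")
})

test_that("sliding-window dispersion is affine invariant", {
  set.seed(6)
  x <- rnorm(400)
  v <- sliding_window_dispersion(x)
  expect_equal(sliding_window_dispersion(3.7 * x - 11), v, tolerance = 1e-10)
  expect_equal(sliding_window_dispersion(-0.2 * x + 5), v, tolerance = 1e-10)
})

test_that("AR-residual autocorrelation uses 25 windows of length 192", {
  set.seed(8)
  x <- as.numeric(stats::filter(rnorm(1920), c(0.5, -0.2),
                                method = "recursive")) + 0.3
  o <- ar_residual_oracle(x)
  expect_equal(o$window_len, 192L)
  expect_equal(o$n_windows, 25L)
  expect_equal(ar_residual_autocorr(x), o$value, tolerance = 1e-10)

  # a different length still matches the oracle
  y <- rnorm(700)
  expect_equal(ar_residual_autocorr(y), ar_residual_oracle(y)$value,
               tolerance = 1e-10)
})

test_that("AR residuals of a correctly specified fit are white", {
  set.seed(9)
  vals <- replicate(5, ar_residual_autocorr(rnorm(1920)))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(vals < 0.1))
  expect_error(ar_residual_autocorr(rnorm(10)), "short")
})

test_that("the feature catalog is fixed-order, deterministic and degenerate-safe", {
  set.seed(10)
  x <- rnorm(1850)
  f1 <- catalog_features(x)
  f2 <- catalog_features(x)
  expect_identical(f1, f2)
  expect_length(f1, 40L)
  expect_named(f1)
  expect_identical(names(catalog_features(rnorm(300))), names(f1))

  cst <- catalog_features(rep(1.5, 1850))
  expect_true(is.nan(cst[["sw_disp_w50_s25"]]))
  expect_true(is.nan(cst[["bp_frac_1"]]))
  expect_true(is.nan(cst[["skewness"]]))
  expect_equal(cst[["argmax_abs_frac"]], 0)
  # band-power fractions sum to one on non-degenerate input
  expect_equal(sum(f1[paste0("bp_frac_", 1:5)]), 1, tolerance = 1e-9)
})

test_that("robust sigmoid normalization follows the median/iqr formula", {
  col <- c(1, 2, 3, 4, 5)
  m <- feature_matrix(cbind(f = col),
                      keys = data.frame(visit_id = paste0("V", 1:5),
                                        anatomy = "APB", side = "L"))
  out <- robust_sigmoid_normalize(m)
  # median 3, iqr 2 (interpolated quantiles): x = 5 -> 1/(1+e^-1.35)
  expect_equal(unname(out$values[5, "f"]), 1 / (1 + exp(-1.35)),
               tolerance = 1e-9)
  expect_equal(unname(out$values[5, "f"]), 0.7941, tolerance = 1e-4)
  # the column median maps to exactly 1/2
  expect_equal(unname(out$values[3, "f"]), 0.5)
  expect_true(all(out$values > 0 & out$values < 1))
})

test_that("normalization discards degenerate columns and is affine stable", {
  set.seed(12)
  x <- rnorm(40)
  vals <- cbind(a = x, b = 2.5 * x - 7, cst = rep(1, 40),
                bad = c(NaN, rnorm(39)))
  m <- feature_matrix(vals, keys = data.frame(visit_id = paste0("V", 1:40),
                                              anatomy = "APB", side = "L"))
  out <- robust_sigmoid_normalize(m)
  expect_setequal(colnames(out$values), c("a", "b"))
  expect_setequal(out$discarded$column, c("cst", "bad"))
  # affine rescaling of a column leaves its normalized values unchanged
  expect_equal(out$values[, "a"], out$values[, "b"], tolerance = 1e-12)
  # monotone: order preserved
  expect_equal(order(out$values[, "a"]), order(x))
})

test_that("left-right summation folds sides into visit-anatomy rows", {
  keys <- expand.grid(side = c("L", "R"), anatomy = c("APB", "AH"),
                      visit_id = c("V1", "V2"), stringsAsFactors = FALSE)
  vals <- matrix(seq(0.1, 0.8, by = 0.1), ncol = 1,
                 dimnames = list(NULL, "f"))
  m <- feature_matrix(vals, keys = keys[, c("visit_id", "anatomy", "side")])
  out <- sum_left_right(m)
  expect_equal(nrow(out$values), 4L)  # 2 visits x 2 anatomies
  i <- which(out$keys$visit_id == "V1" & out$keys$anatomy == "APB")
  expect_equal(unname(out$values[i, "f"]), 0.1 + 0.2)
  # swapping sides leaves the sums unchanged
  m2 <- m
  m2$keys$side <- ifelse(m$keys$side == "L", "R", "L")
  out2 <- sum_left_right(m2)
  expect_equal(out$values[order(out$keys$visit_id, out$keys$anatomy), ],
               out2$values[order(out2$keys$visit_id, out2$keys$anatomy), ])
  # a missing side is an error
  m3 <- feature_matrix(vals[1:3, , drop = FALSE], keys = keys[1:3, c(3, 2, 1)])
  expect_error(sum_left_right(m3), "missing side")
})

test_that("features separate facilitated from quiescent recordings", {
  set.seed(14)
  n <- 100L
  bp <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    fx <- trim_artifact(generate_mep(25, 0.6, facilitated = TRUE)$samples)
    qx <- trim_artifact(generate_mep(25, 0.6, facilitated = FALSE)$samples)
    bp[i, 1] <- catalog_features(fx)[["bp_frac_5"]]
    bp[i, 2] <- catalog_features(qx)[["bp_frac_5"]]
  }
  # the high band carries the contraction noise
  expect_lt(wilcox.test(bp[, 1], bp[, 2])$p.value, 0.01)
})
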