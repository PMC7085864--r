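test_that("AUC equals brute-force pair counting", {
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.4, 0.35, 0.8)
  expect_equal(auc(y, s), 0.75)
  expect_equal(auc(y, c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(y, rep(0.3, 4)), 0.5)

  set.seed(51)
  for (r in 1:20) {
    n <- sample(5:200, 1)
    yy <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(yy)) < 2) next
    ss <- if (r %% 3 == 0) sample(1:5, n, TRUE) else rnorm(n)  # with ties
    expect_equal(auc(yy, ss), auc_bruteforce(yy, ss), tolerance = 1e-12)
  }
  expect_error(auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("DeLong variance matches direct placement-value summation", {
  # 6-sample worked pair
  y <- c(1, 0, 1, 0, 1, 0)
  sa <- c(0.9, 0.2, 0.6, 0.4, 0.7, 0.3)
  sb <- c(0.8, 0.3, 0.5, 0.45, 0.9, 0.1)
  dl <- delong_test(y, sa, sb)
  expect_equal(dl$var_delta, delong_var_bruteforce(y, sa, sb),
               tolerance = 1e-12)

  set.seed(52)
  for (r in 1:10) {
    n <- sample(10:50, 1)
    yy <- rbinom(n, 1, 0.4)
    if (length(unique(yy)) < 2) next
    a <- rnorm(n); b <- a + rnorm(n, 0, 0.5)
    dl <- delong_test(yy, a, b)
    expect_equal(dl$var_delta, max(delong_var_bruteforce(yy, a, b), 0),
                 tolerance = 1e-10)
    expect_equal(dl$auc_a, auc(yy, a))
    expect_equal(dl$auc_b, auc(yy, b))
  }
})

test_that("DeLong agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  y <- rbinom(120, 1, 0.35)
  a <- rnorm(120) + y
  b <- rnorm(120) + 0.5 * y
  dl <- delong_test(y, b, a)   # tests a > b
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE),
                        method = "delong", paired = TRUE,
                        alternative = "greater")
  expect_equal(dl$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
})

test_that("DeLong degenerate cases follow the stated conventions", {
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.1, 0.8, 0.2)
  same <- delong_test(y, s, s)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 0.5)
  # zero variance with zero difference: p = 1/2 by convention
  cst <- delong_test(y, rep(0.5, 4), rep(0.5, 4))
  expect_equal(cst$p_value, 0.5)
  expect_error(delong_test(y, s, s[1:3]), "paired")
})

test_that("grouped splits keep patients on one side and stratify", {
  groups <- c("p1", "p2", "p3", "p4")
  y <- c(1, 0, 1, 0)
  sp <- grouped_stratified_split(groups, y, 0.5, seed = 1)
  expect_length(sp$train, 2L)
  expect_length(sp$test, 2L)
  expect_equal(sum(y[sp$train]), 1)  # one positive on each side
  expect_equal(sum(y[sp$test]), 1)

  set.seed(54)
  for (r in 1:10) {
    g <- sample(paste0("p", 1:12), 60, TRUE)
    yy <- rbinom(60, 1, 0.3)
    if (length(unique(yy)) < 2) next
    frac <- sample(c(0.2, 0.5, 0.8), 1)
    sp <- grouped_stratified_split(g, yy, frac, seed = r)
    expect_length(intersect(g[sp$train], g[sp$test]), 0L)
    expect_setequal(c(sp$train, sp$test), seq_len(60))
  }
  sp1 <- grouped_stratified_split(groups, y, 0.5, seed = 9)
  sp2 <- grouped_stratified_split(groups, y, 0.5, seed = 9)
  expect_identical(sp1$train, sp2$train)
  expect_error(grouped_stratified_split(rep("p", 4), y, 0.5), "two groups")
})

test_that("top-n choice maximizes validation AUC with smallest-n ties", {
  expect_equal(choose_top_n(c(0.6, 0.7, 0.75, 0.7)), 2L)
  expect_equal(choose_top_n(rep(0.5, 5)), 0L)
  expect_equal(choose_top_n(numeric()), 0L)
  expect_equal(choose_top_n(0.5), 0L)  # n_max = 0
})

test_that("a smoke experiment produces consistent records and aggregates", {
  prep <- small_prepared()
  ex <- run_experiment(prep, train_fractions = c(0.5, 0.8), n_outer = 2,
                       n_inner = 2, selection = FALSE,
                       fixed_features = c("sw_disp_w50_s25", "ar2_resid_ac1"),
                       kind = "rf", seed = 77)
  expect_s3_class(ex, "mep_experiment")
  expect_equal(nrow(ex$records), 2 * 2 * 2)
  expect_true(all(ex$records$auc_lit >= 0 & ex$records$auc_lit <= 1))
  expect_true(all(ex$records$p_value >= 0 & ex$records$p_value <= 1))
  agg <- ex$aggregates
  for (fr in unique(agg$train_fraction)) {
    d <- ex$records[ex$records$train_fraction == fr, ]
    expect_equal(agg$auc_ts_mean[agg$train_fraction == fr], mean(d$auc_ts))
    expect_equal(agg$frac_improved[agg$train_fraction == fr],
                 mean(d$delta > 0))
  }
  ss <- significance_summary(ex)
  expect_true(all(ss$frac_improved >= 0 & ss$frac_improved <= 1))
  expect_true(all(ss$frac_significant >= 0 & ss$frac_significant <= 1))
  # determinism of the whole experiment
  ex2 <- run_experiment(prep, train_fractions = c(0.5, 0.8), n_outer = 2,
                        n_inner = 2, selection = FALSE,
                        fixed_features = c("sw_disp_w50_s25", "ar2_resid_ac1"),
                        kind = "rf", seed = 77)
  expect_identical(ex$records, ex2$records)
})

test_that("all p = 0.5 gives a zero significant fraction", {
  ex <- structure(list(records = data.frame(
    train_fraction = 0.5, outer = 1:4, inner = 1,
    auc_lit = 0.6, auc_ts = 0.6, delta = 0, p_value = 0.5)),
    class = "mep_experiment")
  ss <- significance_summary(ex)
  expect_equal(ss$frac_significant, 0)
  expect_equal(ss$frac_improved, 0)
})

test_that("DeLong decisions agree with a paired bootstrap on large samples", {
  set.seed(55)
  boot_p <- function(y, a, b, nboot = 200) {
    deltas <- replicate(nboot, {
      i <- sample(length(y), replace = TRUE)
      if (length(unique(y[i])) < 2) return(NA_real_)
      auc(y[i], b[i]) - auc(y[i], a[i])
    })
    mean(deltas <= 0, na.rm = TRUE)  # one-sided: H1 is delta > 0
  }
  agree <- logical(20)
  for (r in seq_len(20)) {
    n <- 300
    y <- rbinom(n, 1, 0.35)
    a <- rnorm(n) + 0.6 * y
    b <- a + rnorm(n, 0, 0.6) + runif(1, 0, 0.4) * y
    d_dl <- delong_test(y, a, b)$p_value < 0.05
    d_bs <- boot_p(y, a, b) < 0.05
    agree[r] <- d_dl == d_bs
  }
  expect_gte(mean(agree), 0.9)
})

test_that("significance fractions grow with the test-subset size", {
  set.seed(56)
  n <- 600
  groups <- rep(paste0("p", 1:200), each = 3)
  y <- rbinom(n, 1, 0.3)
  lit <- rnorm(n) + 0.4 * y
  # a real but noisy improvement: the paired test needs samples for power
  ts <- lit + 0.25 * y + rnorm(n, 0, 0.8)
  out <- significance_by_test_size(y, lit, ts, groups,
                                   sizes = c(60, 600), n_rep = 40, seed = 2)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$frac_improved >= 0 & out$frac_improved <= 1))
  expect_gt(out$frac_significant[2], out$frac_significant[1])
})
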