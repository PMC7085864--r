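test_that("mutual information matches analytic values", {
  # binary feature identical to the target at prevalence 1/2: ln 2
  y <- rep(c(0L, 1L), 500)
  expect_equal(mutual_information(y, y), log(2), tolerance = 1e-12)

  # 10% symmetric flips at prevalence 1/2: ln2 - H(0.1)
  set.seed(31)
  n <- 100000
  yy <- rbinom(n, 1, 0.5)
  f <- ifelse(runif(n) < 0.1, 1 - yy, yy)
  expected <- log(2) + 0.1 * log(0.1) + 0.9 * log(0.9)
  expect_lt(abs(mutual_information(f, yy) - expected), 0.01)

  # an independently shuffled continuous feature carries ~ no information
  g <- sample(rnorm(2000))
  y2 <- rbinom(2000, 1, 0.5)
  expect_lt(mutual_information(g, y2, seed = 4), 0.02)
  expect_gte(mutual_information(g, y2, seed = 4), 0)

  expect_error(mutual_information(rnorm(50), rep(1, 50)), "both classes")
  expect_error(mutual_information(rnorm(3), c(0, 1)), "equal length")
})

test_that("preselection keeps the ceiling of the top fraction", {
  set.seed(32)
  n <- 300
  y <- rbinom(n, 1, 0.4)
  m <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  m[, 7] <- y + rnorm(n, 0, 0.05)  # near-copy of the target
  kept <- preselect_top_fraction(m, y, fraction = 0.10)
  expect_length(kept, 2L)          # ceil(0.1 * 20)
  expect_true("f7" %in% kept)
  expect_length(preselect_top_fraction(m[, 1:5], y, fraction = 0.10), 1L)
  expect_length(preselect_top_fraction(m, y, fraction = 1), 20L)
  expect_error(preselect_top_fraction(m, y, fraction = 0), "fraction")
})

test_that("correlation distance treats anti-correlation as closeness", {
  u <- rnorm(50)
  expect_equal(correlation_distance(u, u), 0)
  expect_equal(correlation_distance(u, -u), 0)
  expect_equal(correlation_distance(u, 2 * u + 3), 0, tolerance = 1e-12)
  expect_equal(correlation_distance(c(1, -1, 1, -1), c(1, 1, -1, -1)), 1)
  expect_error(correlation_distance(rep(1, 50), u), "constant")
  # symmetry
  v <- rnorm(50)
  expect_equal(correlation_distance(u, v), correlation_distance(v, u))
})

test_that("clustering keeps one representative per correlated group", {
  set.seed(33)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  base <- rnorm(n)
  m <- cbind(a = base, b = base + rnorm(n, 0, 1e-6), c = rnorm(n))
  expect_length(cluster_reduce(m, y), 2L)

  trio <- cbind(a = base, b = base + rnorm(n, 0, 0.1),
                c = -base + rnorm(n, 0, 0.1))
  stopifnot(min(abs(cor(trio))) >= 0.95)
  expect_length(cluster_reduce(trio, y), 1L)

  ind <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  stopifnot(max(abs(cor(ind)[upper.tri(diag(4))])) < 0.9)
  expect_length(cluster_reduce(ind, y), 4L)
  expect_equal(cluster_reduce(ind[, 1, drop = FALSE], y), "a")
})

test_that("Boruta confirms a planted signal and is deterministic", {
  set.seed(34)
  n <- 250
  y <- rbinom(n, 1, 0.5)
  confirmed <- logical(10)
  for (r in 1:10) {
    m <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("noise", 1:20)))
    m <- cbind(m, signal = y + rnorm(n, 0, 0.3))
    rep <- boruta(m, y, max_iter = 30, seed = r)
    confirmed[r] <- rep$decision[["signal"]] == "Confirmed"
  }
  expect_gte(mean(confirmed), 0.9)

  m <- matrix(rnorm(200 * 5), 200, 5)
  y2 <- rbinom(200, 1, 0.5)
  r1 <- boruta(m, y2, max_iter = 15, seed = 9)
  r2 <- boruta(m, y2, max_iter = 15, seed = 9)
  expect_identical(r1$decision, r2$decision)
  expect_identical(r1$hits, r2$hits)
  expect_error(boruta(m, rep(0L, 200)), "both classes")
})

test_that("Boruta's false-confirmation rate is controlled under the null", {
  set.seed(35)
  n_runs <- 30L
  false_conf <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    m <- matrix(rnorm(150 * 8), 150, 8, dimnames = list(NULL, paste0("f", 1:8)))
    y <- rbinom(150, 1, 0.5)
    rep <- boruta(m, y, max_iter = 25, seed = 100 + r)
    false_conf[r] <- mean(rep$decision == "Confirmed")
  }
  expect_lte(mean(false_conf), 2 * 0.05)
})

test_that("ranking returns the top confirmed features", {
  rep <- structure(list(
    decision = c(a = "Confirmed", b = "Confirmed", c = "Rejected",
                 d = "Confirmed", e = "Tentative"),
    mean_importance = c(a = 2, b = 5, c = 9, d = 3, e = 4)),
    class = "boruta_report")
  expect_equal(rank_and_take(rep, 2), c("b", "d"))
  expect_equal(rank_and_take(rep, 6), c("b", "d", "a"))  # all confirmed
  expect_equal(rank_and_take(rep, 0), character())
  expect_equal(rank_and_take(rep, 2, within = c("a", "d")), c("d", "a"))
})

test_that("the cascade output is monotone (each stage shrinks the set)", {
  prep <- small_prepared()
  sel <- select_features(prep$ts$APB, prep$lit$APB, prep$y,
                         mi_fraction = 0.5, max_iter = 15, seed = 3)
  expect_true(all(sel$cluster_survivors %in% sel$preselected))
  expect_true(all(sel$preselected %in% names(sel$mi_scores)))
  expect_true(all(sel$ranked_ts %in% sel$cluster_survivors))
  conf <- names(sel$boruta$decision)[sel$boruta$decision == "Confirmed"]
  expect_true(all(sel$ranked_ts %in% conf))
})
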