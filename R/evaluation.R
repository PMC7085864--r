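# Evaluation engine: ROC AUC, the paired DeLong test, grouped stratified
# shuffle splits, validation-based top-n selection, and the full
# experiment over train fractions.

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive sample outranks a
#' randomly chosen negative one, with ties counted one half (midrank
#' formula).
#'
#' @param y Binary labels (0/1), both classes present.
#' @param scores Numeric scores, higher = more positive.
#' @return Scalar in `[0, 1]`.
#' @export
auc <- function(y, scores) {
  y <- as.integer(y)
  if (length(y) != length(scores)) stop("unequal lengths", call. = FALSE)
  m <- sum(y == 1L); n <- sum(y == 0L)
  if (m == 0L || n == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1L]) - m * (m + 1) / 2) / (m * n)
}

# Placement values of one score vector: V10 (per positive) and V01
# (per negative).
placements <- function(y, s) {
  xp <- s[y == 1L]
  xn <- s[y == 0L]
  psi <- outer(xp, xn, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' Paired DeLong test for the difference of two correlated AUCs
#'
#' Tests, one-sided, whether the true AUC of model B exceeds that of
#' model A when both are evaluated on the same samples. The variance of
#' the AUC difference is estimated from the structural components
#' (placement values) of the two score vectors. When the difference and
#' its variance are both zero the p-value is 0.5 by convention.
#'
#' @param y Binary labels (0/1).
#' @param scores_a,scores_b Paired score vectors on the same samples.
#' @return A `delong_test` object: `auc_a`, `auc_b`, `delta`
#'   (`auc_b - auc_a`), `var_delta`, `z`, and the one-sided `p_value` for
#'   the alternative `delta > 0`.
#' @export
delong_test <- function(y, scores_a, scores_b) {
  y <- as.integer(y)
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    stop("scores must be paired with 'y' (equal lengths)", call. = FALSE)
  }
  m <- sum(y == 1L); n <- sum(y == 0L)
  if (m == 0L || n == 0L) stop("both classes must be present", call. = FALSE)
  pa <- placements(y, scores_a)
  pb <- placements(y, scores_b)
  auc_a <- mean(pa$v10)
  auc_b <- mean(pb$v10)
  delta <- auc_b - auc_a
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  var_delta <- max(var_delta, 0)
  if (var_delta == 0) {
    p <- if (delta == 0) 0.5 else if (delta > 0) 0 else 1
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_delta)
    p <- 1 - stats::pnorm(z)
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, delta = delta,
                 var_delta = var_delta, z = z, p_value = p),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test: AUC_A = %.4f, AUC_B = %.4f, delta = %+.4f\n",
              x$auc_a, x$auc_b, x$delta))
  cat(sprintf("  z = %.3f, one-sided p (B > A) = %.4g\n", x$z, x$p_value))
  invisible(x)
}

#' Grouped stratified shuffle split
#'
#' Randomly assigns whole groups (patients) to the training or the test
#' side so that the training side holds approximately `train_fraction` of
#' the samples and the positive-target rate is roughly equal on both
#' sides. Exact stratification is impossible under the grouping
#' constraint, so `n_candidates` random assignments are drawn and the one
#' with the smallest stratification error near the target fraction is
#' kept. Deterministic given the seed.
#'
#' @param groups Group (patient) identifier per sample.
#' @param y Binary targets.
#' @param train_fraction Target fraction of samples on the training side.
#' @param seed RNG seed.
#' @param n_candidates Random assignments to score (default 200).
#' @return A `split_plan`: `train`, `test` (sample indices), the group
#'   sets, and the realized fraction and positive rates.
#' @export
grouped_stratified_split <- function(groups, y, train_fraction, seed = 1L,
                                     n_candidates = 200L) {
  y <- as.integer(y)
  ug <- unique(groups)
  if (length(ug) < 2L) stop("need at least two groups", call. = FALSE)
  n <- length(y)
  pos_all <- mean(y)
  g_n <- tapply(rep(1L, n), groups, sum)[ug]
  g_pos <- tapply(y, groups, sum)[ug]
  best <- NULL
  best_score <- Inf
  with_seed(seed, {
    for (cand in seq_len(n_candidates)) {
      perm <- sample(length(ug))
      csum <- cumsum(g_n[perm])
      k <- which.min(abs(csum - train_fraction * n))
      tr_groups <- perm[seq_len(k)]
      n_tr <- csum[k]
      pos_tr <- sum(g_pos[tr_groups]) / n_tr
      pos_te <- (sum(g_pos) - sum(g_pos[tr_groups])) / (n - n_tr)
      score <- abs(pos_tr - pos_all) + abs(pos_te - pos_all) +
        0.5 * abs(n_tr / n - train_fraction)
      if (score < best_score) {
        best_score <- score
        best <- ug[tr_groups]
      }
    }
  })
  in_train <- groups %in% best
  structure(
    list(train = which(in_train), test = which(!in_train),
         train_groups = best, test_groups = setdiff(ug, best),
         train_fraction = train_fraction,
         realized_fraction = mean(in_train),
         pos_rate_all = pos_all,
         pos_rate_train = mean(y[in_train]),
         pos_rate_test = mean(y[!in_train]),
         stratification_error = best_score, seed = seed),
    class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test samples (target fraction %.2f, realized %.3f)\n",
              length(x$train), length(x$test), x$train_fraction,
              x$realized_fraction))
  cat(sprintf("  positive rate: all %.3f, train %.3f, test %.3f\n",
              x$pos_rate_all, x$pos_rate_train, x$pos_rate_test))
  invisible(x)
}

#' Choose the number of extra time-series features on validation AUCs
#'
#' Given mean validation AUCs for candidate models using the top
#' 0, 1, ..., n_max ranked time-series features, returns the `n`
#' maximizing the AUC; the smallest `n` wins on ties.
#'
#' @param val_aucs Numeric vector of validation AUCs indexed by
#'   `n = 0 .. length(val_aucs) - 1`.
#' @return The chosen `n` (integer, 0-based).
#' @export
choose_top_n <- function(val_aucs) {
  if (length(val_aucs) == 0L) return(0L)
  which(val_aucs == max(val_aucs))[1L] - 1L
}

#' Run the grouped-split evaluation experiment
#'
#' For each train fraction and each of `n_outer` grouped stratified
#' shuffle splits: the feature-selection cascade is refit on training
#' rows only; per-anatomy classifiers are trained with the literature
#' covariates plus the top 0..n_max ranked time-series features; then for
#' each of `n_inner` grouped stratified halvings of the test set the
#' number of extra features is chosen on the validation half and the
#' literature-only and augmented models are scored on the evaluation
#' half, including the paired DeLong test. One model set is trained per
#' outer split and evaluated across all inner splits; only the top-n
#' choice varies per inner split.
#'
#' @param prepared A prepared analysis data set from [prepare_cohort()].
#' @param train_fractions Fractions of the data used for training.
#' @param n_outer,n_inner Outer and inner split counts. The desk-scale
#'   defaults (20 and 5) keep a full run fast; the protocol itself scales
#'   to arbitrarily many splits.
#' @param n_max Maximum number of extra time-series features (default 6).
#' @param kind Classifier, `"rf"` or `"lr"`.
#' @param selection Run the selection cascade per split (`TRUE`), or use
#'   `fixed_features` for all splits.
#' @param fixed_features Character vector of time-series features to use
#'   when `selection = FALSE` (ranked order).
#' @param mi_fraction,cluster_cutoff,n_trees,boruta_max_iter,alpha,boruta_drop_confirmed
#'   Cascade settings, see [select_features()].
#' @param seed RNG seed controlling all splits, selection and training.
#' @return An `mep_experiment`: per-split records, per-fraction
#'   aggregates, and the per-split selection reports.
#' @export
run_experiment <- function(prepared,
                           train_fractions = c(0.2, 0.3, 0.5, 0.8),
                           n_outer = 20L, n_inner = 5L, n_max = 6L,
                           kind = c("rf", "lr"), selection = TRUE,
                           fixed_features = NULL,
                           mi_fraction = 0.10, cluster_cutoff = 0.1,
                           n_trees = 100L, boruta_max_iter = 100L,
                           boruta_drop_confirmed = FALSE,
                           alpha = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  y <- prepared$y
  groups <- prepared$groups
  anatomies <- names(prepared$ts)
  records <- list()
  selections <- list()

  for (fi in seq_along(train_fractions)) {
    frac <- train_fractions[fi]
    for (os in seq_len(n_outer)) {
      sp <- tryCatch(
        grouped_stratified_split(groups, y, frac,
                                 seed = child_seed(seed, fi * 1000L + os)),
        error = function(e) NULL)
      if (is.null(sp) || sum(y[sp$train] == 1L) < 2L ||
          sum(y[sp$test] == 1L) < 4L) {
        warning(sprintf("skipping fraction %.2f split %d: insufficient samples",
                        frac, os))
        next
      }
      tr <- sp$train

      ranked <- list()
      for (an in anatomies) {
        if (selection) {
          sel <- select_features(prepared$ts[[an]][tr, , drop = FALSE],
                                 prepared$lit[[an]][tr, , drop = FALSE],
                                 y[tr], mi_fraction = mi_fraction,
                                 cluster_cutoff = cluster_cutoff, k = n_max,
                                 n_trees = n_trees,
                                 max_iter = boruta_max_iter,
                                 drop_confirmed = boruta_drop_confirmed,
                                 alpha = alpha,
                                 seed = child_seed(seed, fi * 100000L + os * 10L +
                                                     match(an, anatomies)))
          ranked[[an]] <- sel$ranked_ts
          selections[[sprintf("%s_%.2f_%d", an, frac, os)]] <- sel
        } else {
          ranked[[an]] <- utils::head(
            intersect(fixed_features %||% character(),
                      colnames(prepared$ts[[an]])), n_max)
        }
      }
      n_cand <- min(n_max, min(lengths(ranked)))

      # one model per candidate n, trained once per outer split
      models <- lapply(0:n_cand, function(nn) {
        xb <- lapply(anatomies, function(an) {
          cbind(prepared$lit[[an]],
                prepared$ts[[an]][, utils::head(ranked[[an]], nn),
                                  drop = FALSE])
        })
        names(xb) <- anatomies
        fit_progression(lapply(xb, function(m) m[tr, , drop = FALSE]), y[tr],
                        kind = kind, n_trees = n_trees,
                        seed = child_seed(seed, fi * 7919L + os))
      })
      # predictions on the full test side, reused across inner splits
      preds <- lapply(models, function(mod) {
        xb <- lapply(anatomies, function(an) {
          cbind(prepared$lit[[an]],
                prepared$ts[[an]][, mod$ts_features[[an]], drop = FALSE])
        })
        names(xb) <- anatomies
        predict(mod, lapply(xb, function(m) m[sp$test, , drop = FALSE]))
      })

      te_y <- y[sp$test]
      te_groups <- groups[sp$test]
      for (is in seq_len(n_inner)) {
        isp <- tryCatch(
          grouped_stratified_split(te_groups, te_y, 0.5,
                                   seed = child_seed(seed,
                                                     fi * 31L + os * 997L + is)),
          error = function(e) NULL)
        if (is.null(isp)) next
        val <- isp$train; ev <- isp$test
        if (length(unique(te_y[val])) < 2L ||
            length(unique(te_y[ev])) < 2L) next
        val_aucs <- vapply(preds, function(p) auc(te_y[val], p[val]),
                           numeric(1))
        n_star <- choose_top_n(val_aucs)
        p_lit <- preds[[1L]][ev]
        p_ts <- preds[[n_star + 1L]][ev]
        dl <- delong_test(te_y[ev], p_lit, p_ts)
        records[[length(records) + 1L]] <- data.frame(
          train_fraction = frac, outer = os, inner = is, n_chosen = n_star,
          auc_lit = dl$auc_a, auc_ts = dl$auc_b, delta = dl$delta,
          p_value = dl$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  structure(
    list(records = records,
         aggregates = aggregate_records(records),
         selections = selections,
         config = list(train_fractions = train_fractions, n_outer = n_outer,
                       n_inner = n_inner, n_max = n_max, kind = kind,
                       selection = selection, seed = seed)),
    class = "mep_experiment")
}

aggregate_records <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(NULL)
  do.call(rbind, lapply(split(records, records$train_fraction), function(d) {
    data.frame(train_fraction = d$train_fraction[1],
               n_records = nrow(d),
               auc_lit_mean = mean(d$auc_lit), auc_lit_sd = stats::sd(d$auc_lit),
               auc_ts_mean = mean(d$auc_ts), auc_ts_sd = stats::sd(d$auc_ts),
               frac_improved = mean(d$delta > 0),
               frac_significant = mean(d$p_value < 0.05),
               stringsAsFactors = FALSE)
  }))
}

#' Fractions of improved and significantly improved splits
#'
#' @param result An `mep_experiment`.
#' @param alpha Significance level (default 0.05).
#' @return Data frame per train fraction with the fraction of splits
#'   whose AUC improved when adding time-series features, and the
#'   fraction significantly improved under the one-sided DeLong test.
#' @export
significance_summary <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "mep_experiment"))
  d <- result$records
  out <- do.call(rbind, lapply(split(d, d$train_fraction), function(g) {
    data.frame(train_fraction = g$train_fraction[1],
               frac_improved = mean(g$delta > 0),
               frac_significant = mean(g$p_value < alpha),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.mep_experiment <- function(x, ...) {
  cat(sprintf("<mep_experiment> %s, %d records\n", x$config$kind,
              nrow(x$records)))
  if (!is.null(x$aggregates)) {
    print(x$aggregates, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
plot.mep_experiment <- function(x, ...) {
  a <- x$aggregates
  if (is.null(a)) stop("empty experiment", call. = FALSE)
  ylim <- range(a$auc_lit_mean - a$auc_lit_sd, a$auc_ts_mean + a$auc_ts_sd,
                0.5)
  graphics::plot(a$train_fraction, a$auc_ts_mean, type = "b", pch = 19,
                 ylim = ylim, xlab = "train fraction", ylab = "test AUC",
                 main = sprintf("Learning curve (%s)", x$config$kind), ...)
  graphics::arrows(a$train_fraction, a$auc_ts_mean - a$auc_ts_sd,
                   a$train_fraction, a$auc_ts_mean + a$auc_ts_sd,
                   angle = 90, code = 3, length = 0.03)
  graphics::lines(a$train_fraction, a$auc_lit_mean, type = "b", pch = 1,
                  lty = 2)
  graphics::legend("bottomright", legend = c("literature + TS", "literature"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Significance fractions on test subsets of growing size
#'
#' The power view of the paired comparison: a single fixed pair of score
#' vectors (literature-only vs augmented model, evaluated on held-out
#' samples) is re-tested on random grouped subsets of increasing size;
#' for each size the fractions of subsets showing an improvement and a
#' significant improvement are reported. As the subset grows the test
#' gains power, so the significant fraction should rise toward the
#' improvement fraction.
#'
#' @param y Held-out binary labels.
#' @param scores_lit,scores_ts Paired scores of the two models.
#' @param groups Patient identifiers (subsets never split a patient).
#' @param sizes Approximate subset sizes (sample counts).
#' @param n_rep Random subsets per size (default 50).
#' @param alpha Significance level (default 0.05).
#' @param seed RNG seed.
#' @return Data frame: size, realized mean size, `frac_improved`,
#'   `frac_significant`.
#' @export
significance_by_test_size <- function(y, scores_lit, scores_ts, groups,
                                      sizes, n_rep = 50L, alpha = 0.05,
                                      seed = 1L) {
  y <- as.integer(y)
  ug <- unique(groups)
  out <- vector("list", length(sizes))
  with_seed(seed, {
    for (si in seq_along(sizes)) {
      sz <- sizes[si]
      imp <- sig <- rep(NA, n_rep)
      realized <- numeric(n_rep)
      for (r in seq_len(n_rep)) {
        perm <- sample(ug)
        csum <- cumsum(tapply(rep(1L, length(y)), groups, sum)[perm])
        k <- which.min(abs(csum - sz))
        idx <- which(groups %in% perm[seq_len(k)])
        realized[r] <- length(idx)
        if (length(unique(y[idx])) < 2L) next
        dl <- delong_test(y[idx], scores_lit[idx], scores_ts[idx])
        imp[r] <- dl$delta > 0
        sig[r] <- dl$p_value < alpha
      }
      out[[si]] <- data.frame(size = sz, mean_size = mean(realized),
                              frac_improved = mean(imp, na.rm = TRUE),
                              frac_significant = mean(sig, na.rm = TRUE))
    }
  })
  do.call(rbind, out)
}
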