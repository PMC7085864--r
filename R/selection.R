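# Feature-selection cascade: mutual-information preselection,
# correlation-distance clustering, Boruta shadow-feature selection,
# top-k ranking.

#' Mutual information between a feature and a binary target
#'
#' Returns a nonnegative estimate in nats. Features with at most 32
#' distinct values use the discrete plug-in estimator on the contingency
#' table; continuous features use the nearest-neighbour
#' continuous-discrete estimator (Ross 2014, k = 3) with a tiny seeded
#' jitter to break ties.
#'
#' @param f Numeric feature column.
#' @param y Binary target (0/1), both classes present.
#' @param k Neighbour count for the continuous estimator.
#' @param seed Seed for the tie-break jitter.
#' @return Scalar MI estimate (nats), clamped at 0.
#' @export
mutual_information <- function(f, y, k = 3L, seed = 1L) {
  if (length(f) != length(y)) stop("'f' and 'y' must have equal length",
                                   call. = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("'y' must contain both classes",
                                   call. = FALSE)
  if (length(unique(f)) <= 32L) {
    return(mi_plugin(f, y))
  }
  mi_knn(f, y, k = k, seed = seed)
}

mi_plugin <- function(f, y) {
  tab <- table(f, y)
  p <- tab / sum(tab)
  pr <- rowSums(p)
  pc <- colSums(p)
  e <- outer(pr, pc)
  nz <- p > 0
  max(0, sum(p[nz] * log(p[nz] / e[nz])))
}

# Ross (2014) kNN estimator for continuous feature / discrete target.
mi_knn <- function(f, y, k = 3L, seed = 1L) {
  n <- length(f)
  x <- with_seed(seed, f + stats::rnorm(n, 0, 1e-10 * max(stats::sd(f), 1e-12)))
  classes <- unique(y)
  d_k <- numeric(n)
  n_y <- numeric(n)
  for (c in classes) {
    idx <- which(y == c)
    if (length(idx) <= k) {
      stop(sprintf("class %s has too few points for k = %d", c, k),
           call. = FALSE)
    }
    ord <- order(x[idx])
    xs <- x[idx][ord]
    m <- length(xs)
    # In 1D the k nearest neighbours of xs[i] form a contiguous window:
    # the k-th NN distance is the smallest, over the k+1 windows of k
    # neighbours around position i, of the larger one-sided distance.
    at <- function(i) ifelse(i >= 1L & i <= m, xs[pmin(pmax(i, 1L), m)],
                             NA_real_)
    pos <- seq_len(m)
    dk_sorted <- rep(Inf, m)
    for (w in 0:k) {
      right <- at(pos + (k - w)) - xs
      left <- xs - at(pos - w)
      cand <- pmax(right, left)
      cand[is.na(cand)] <- Inf
      dk_sorted <- pmin(dk_sorted, cand)
    }
    d_k[idx[ord]] <- dk_sorted
    n_y[idx] <- m
  }
  xs_all <- sort(x)
  # count of points (excluding self) within the class-kNN distance; the
  # small inflation guards against floating-point loss when the boundary
  # neighbour sits at exactly that distance
  eps <- 1e-9 * (max(xs_all) - min(xs_all)) + 1e-300
  m_i <- findInterval(x + d_k + eps, xs_all) -
    findInterval(x - d_k - eps, xs_all, left.open = TRUE) - 1L
  m_i <- pmax(m_i, 1L)
  est <- digamma(n) - mean(digamma(n_y)) + digamma(k) - mean(digamma(m_i))
  max(0, est)
}

#' Preselect the top fraction of features by mutual information
#'
#' Ranks the columns of a feature matrix by mutual information with the
#' target and keeps the top `fraction` (default ten percent, rounded up).
#' Ties keep the original column order.
#'
#' @param m A `feature_matrix` or numeric matrix.
#' @param y Binary target.
#' @param fraction Fraction of features to retain, in (0, 1].
#' @param seed Seed passed to [mutual_information()].
#' @return Character vector of retained feature names, and the MI scores
#'   as a `scores` attribute.
#' @export
preselect_top_fraction <- function(m, y, fraction = 0.10, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  }
  vals <- if (inherits(m, "feature_matrix")) m$values else m
  mi <- vapply(seq_len(ncol(vals)), function(j) {
    mutual_information(vals[, j], y, seed = child_seed(seed, j))
  }, numeric(1))
  names(mi) <- colnames(vals)
  n_keep <- ceiling(fraction * ncol(vals))
  ord <- order(-mi, seq_along(mi))
  kept <- sort(ord[seq_len(n_keep)])
  structure(colnames(vals)[kept], scores = mi)
}

#' Correlation distance between two feature columns
#'
#' `1 - |Pearson correlation|`: highly correlated or anti-correlated
#' features have a distance close to zero, uncorrelated features a
#' distance close to one.
#'
#' @param u,v Numeric vectors of equal length, non-constant.
#' @return Scalar in `[0, 1]`.
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v)) stop("unequal lengths", call. = FALSE)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("correlation distance undefined for a constant input", call. = FALSE)
  }
  d <- 1 - abs(stats::cor(u, v))
  min(max(d, 0), 1)
}

#' Reduce redundant features by correlation-distance clustering
#'
#' Complete-linkage agglomerative clustering on the pairwise correlation
#' distance (`1 - |rho|`), cut at `cutoff`; with complete linkage every
#' within-cluster pair is guaranteed distance at most the merge height,
#' so members of one cluster are mutually highly (anti-)correlated. One
#' representative is kept per cluster: the member with the highest mutual
#' information with the target.
#'
#' @param m A `feature_matrix` or numeric matrix.
#' @param y Binary target (used to pick representatives).
#' @param cutoff Tree cut height (default 0.1).
#' @param seed Seed for the MI estimator.
#' @param mi Optional precomputed MI scores named by feature (avoids
#'   re-estimation when the preselection stage already computed them).
#' @return Character vector of surviving feature names, original order.
#' @export
cluster_reduce <- function(m, y, cutoff = 0.1, seed = 1L, mi = NULL) {
  vals <- if (inherits(m, "feature_matrix")) m$values else m
  p <- ncol(vals)
  if (p == 0L) return(character())
  if (p == 1L) return(colnames(vals))
  d <- 1 - abs(stats::cor(vals))
  d[!is.finite(d)] <- 1
  cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "complete"),
                      h = cutoff)
  if (is.null(mi)) {
    mi <- vapply(seq_len(p), function(j) {
      mutual_information(vals[, j], y, seed = child_seed(seed, j))
    }, numeric(1))
  } else {
    mi <- as.numeric(mi[colnames(vals)])
  }
  keep <- vapply(split(seq_len(p), cl), function(idx) {
    idx[order(-mi[idx], idx)][1L]
  }, integer(1))
  colnames(vals)[sort(keep)]
}

#' Boruta all-relevant feature selection with shadow features
#'
#' Iteratively compares each feature's importance with shuffled copies of
#' all features ("shadows"). Each round a shuffled shadow of every live
#' feature is appended, a random forest is fitted, and importance is
#' measured as the z-score of the permutation (mean decrease in accuracy)
#' importance. Features whose importance exceeds the maximal shadow
#' importance accumulate hits; a two-sided binomial test at `alpha` with
#' Bonferroni correction over the initial feature count confirms or
#' rejects features. Rejected features leave the pool. The procedure
#' stops when every feature is resolved or after `max_iter` rounds
#' (remaining features stay Tentative).
#'
#' @param m A `feature_matrix` or numeric matrix of candidates.
#' @param y Binary target (0/1), both classes present.
#' @param n_trees Trees per random forest (default 100).
#' @param max_iter Maximum number of rounds (default 100).
#' @param alpha Significance level of the binomial test (default 0.05).
#' @param seed RNG seed; the run is deterministic given the seed.
#' @param drop_confirmed If `TRUE`, confirmed features leave the forest
#'   along with the rejected ones, so later rounds (typically spent
#'   resolving one or two borderline features) run on a much smaller
#'   forest. The default `FALSE` keeps confirmed features as context, as
#'   the reference algorithm does. The decision rule is identical either
#'   way; with fewer live features the shadow pool shrinks, and the
#'   binomial test (which assumes a null hit probability of one half, an
#'   upper bound on the true null probability `1/(shadows + 1)`) stays
#'   conservative.
#' @return A `boruta_report`: per-feature decision
#'   (Confirmed/Rejected/Tentative), hit counts, rounds run, and the mean
#'   importance z-score per feature.
#' @export
boruta <- function(m, y, n_trees = 100L, max_iter = 100L, alpha = 0.05,
                   seed = 1L, drop_confirmed = FALSE) {
  vals <- if (inherits(m, "feature_matrix")) m$values else m
  if (is.null(colnames(vals))) colnames(vals) <- paste0("f", seq_len(ncol(vals)))
  y <- factor(as.integer(y), levels = c(0L, 1L))
  if (nlevels(droplevels(y)) < 2L) stop("'y' must contain both classes",
                                        call. = FALSE)
  p0 <- ncol(vals)
  if (p0 == 0L) stop("no candidate features", call. = FALSE)
  feats <- colnames(vals)
  decision <- stats::setNames(rep("Tentative", p0), feats)
  hits <- stats::setNames(rep(0L, p0), feats)
  tested <- stats::setNames(rep(0L, p0), feats)
  imp_sum <- stats::setNames(rep(0, p0), feats)
  imp_n <- stats::setNames(rep(0L, p0), feats)
  thresh <- alpha / (2 * p0)  # two-sided, Bonferroni over features

  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      open <- feats[decision == "Tentative"]
      if (length(open) == 0L) break
      live <- if (drop_confirmed) open else feats[decision != "Rejected"]
      xl <- vals[, live, drop = FALSE]
      shadows <- apply(xl, 2L, sample)
      colnames(shadows) <- paste0(".shadow.", live)
      xx <- cbind(xl, shadows)
      rf <- randomForest::randomForest(xx, y, ntree = n_trees,
                                       importance = TRUE)
      z <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
      z[!is.finite(z)] <- 0
      z_live <- z[live]
      z_shadow_max <- max(z[colnames(shadows)])
      hit <- z_live > z_shadow_max
      hits[live] <- hits[live] + as.integer(hit)
      tested[live] <- tested[live] + 1L
      imp_sum[live] <- imp_sum[live] + z_live
      imp_n[live] <- imp_n[live] + 1L

      for (f in open) {
        p_conf <- stats::pbinom(hits[f] - 1L, tested[f], 0.5,
                                lower.tail = FALSE)
        p_rej <- stats::pbinom(hits[f], tested[f], 0.5)
        if (p_conf < thresh) decision[f] <- "Confirmed"
        else if (p_rej < thresh) decision[f] <- "Rejected"
      }
    }
  })

  structure(
    list(decision = decision, hits = hits, rounds = tested,
         mean_importance = ifelse(imp_n > 0, imp_sum / pmax(imp_n, 1L), NA_real_),
         n_trees = n_trees, alpha = alpha, seed = seed),
    class = "boruta_report")
}

#' @export
print.boruta_report <- function(x, ...) {
  tab <- table(factor(x$decision, levels = c("Confirmed", "Tentative",
                                             "Rejected")))
  cat(sprintf("<boruta_report> %d features: %d confirmed, %d tentative, %d rejected\n",
              length(x$decision), tab[1], tab[2], tab[3]))
  conf <- names(x$decision)[x$decision == "Confirmed"]
  if (length(conf)) {
    ord <- conf[order(-x$mean_importance[conf])]
    cat("  top confirmed:", paste(utils::head(ord, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rank confirmed features and take the top k
#'
#' Orders the Boruta-confirmed features by mean importance z-score and
#' returns the `k` most important (all of them if fewer are confirmed).
#' Ties keep the original feature order.
#'
#' @param report A `boruta_report`.
#' @param k Number of features to return (default 6).
#' @param within Optional restriction of the candidate set (e.g. the
#'   time-series features, excluding literature covariates).
#' @return Character vector of at most `k` feature names, most important
#'   first.
#' @export
rank_and_take <- function(report, k = 6L, within = NULL) {
  stopifnot(inherits(report, "boruta_report"))
  if (k <= 0L) return(character())
  conf <- names(report$decision)[report$decision == "Confirmed"]
  if (!is.null(within)) conf <- intersect(conf, within)
  if (length(conf) == 0L) return(character())
  imp <- report$mean_importance[conf]
  conf <- conf[order(-imp, match(conf, names(report$decision)))]
  utils::head(conf, k)
}

#' Run the full feature-selection cascade
#'
#' Mutual-information preselection of the top fraction of time-series
#' features, correlation-distance clustering with one representative per
#' cluster, then Boruta on the surviving time-series features together
#' with the literature covariates, and finally a top-k ranking of the
#' confirmed time-series features. Literature covariates are always part
#' of the downstream model and serve in Boruta both as a validity check
#' (they are known to be relevant) and as context for features that are
#' only informative jointly.
#'
#' @param ts_matrix Numeric matrix of time-series features (rows =
#'   visits).
#' @param lit_matrix Numeric matrix of literature covariates, same rows.
#' @param y Binary target.
#' @param mi_fraction Preselection fraction (default 0.10).
#' @param cluster_cutoff Clustering cut height (default 0.1).
#' @param k Number of ranked time-series features (default 6).
#' @param n_trees,max_iter,alpha,drop_confirmed Boruta settings, see
#'   [boruta()].
#' @param seed RNG seed.
#' @return A `selection_report`: MI scores, preselected and clustered
#'   survivors, the `boruta_report`, and the ranked time-series features.
#' @export
select_features <- function(ts_matrix, lit_matrix, y, mi_fraction = 0.10,
                            cluster_cutoff = 0.1, k = 6L, n_trees = 100L,
                            max_iter = 100L, alpha = 0.05, seed = 1L,
                            drop_confirmed = FALSE) {
  pre <- preselect_top_fraction(ts_matrix, y, fraction = mi_fraction,
                                seed = child_seed(seed, 1L))
  mi_scores <- attr(pre, "scores")
  kept <- cluster_reduce(ts_matrix[, pre, drop = FALSE], y,
                         cutoff = cluster_cutoff,
                         seed = child_seed(seed, 2L), mi = mi_scores)
  cand <- cbind(ts_matrix[, kept, drop = FALSE], lit_matrix)
  rep <- boruta(cand, y, n_trees = n_trees, max_iter = max_iter,
                alpha = alpha, seed = child_seed(seed, 3L),
                drop_confirmed = drop_confirmed)
  ranked <- rank_and_take(rep, k = k, within = kept)
  structure(
    list(mi_scores = mi_scores, preselected = as.character(pre),
         cluster_survivors = kept, boruta = rep, ranked_ts = ranked,
         literature = colnames(lit_matrix)),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d -> %d (MI) -> %d (clustering) -> %d ranked\n",
              length(x$mi_scores), length(x$preselected),
              length(x$cluster_survivors), length(x$ranked_ts)))
  if (length(x$ranked_ts)) {
    cat("  ranked:", paste(x$ranked_ts, collapse = ", "), "\n")
  }
  invisible(x)
}
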