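# Disability-progression labelling: the two-threshold EDSS rule, the
# two-year follow-up pairing, and sample construction.

DAYS_PER_YEAR <- 365.25

#' Disability progression label from an EDSS pair
#'
#' Standard definition of disability progression: the patient has
#' progressed if `EDSS_T1 - EDSS_T0 >= 1.0` when the baseline
#' `EDSS_T0 <= 5.5`, or `>= 0.5` when the baseline is above 5.5. No
#' confirmation of progression is applied.
#'
#' @param edss_t0,edss_t1 Baseline and follow-up EDSS, on the 0-10 scale in
#'   0.5 steps. Vectorized.
#' @return Integer vector of 0/1 labels.
#' @export
progression_label <- function(edss_t0, edss_t1) {
  check_edss <- function(e, name) {
    bad <- !is.finite(e) | e < 0 | e > 10 | abs(e * 2 - round(e * 2)) > 1e-8
    if (any(bad)) {
      stop(sprintf("'%s' contains values off the EDSS scale (0-10 in 0.5 steps)",
                   name), call. = FALSE)
    }
  }
  check_edss(edss_t0, "edss_t0")
  check_edss(edss_t1, "edss_t1")
  delta <- edss_t1 - edss_t0
  as.integer(ifelse(edss_t0 <= 5.5, delta >= 1.0, delta >= 0.5))
}

#' Select the two-year follow-up EDSS measurement
#'
#' Among EDSS measurements between 1.5 and 3 years after the baseline
#' date, returns the one closest to the 2-year mark. Ties are broken in
#' favor of the earlier measurement.
#'
#' @param history Data frame with columns `date` (Date) and `edss`,
#'   time-sorted.
#' @param t0_date Baseline date.
#' @return A list with `date`, `edss` and `offset_years`, or `NULL` if no
#'   measurement lies in the window.
#' @export
select_t1 <- function(history, t0_date) {
  off <- as.numeric(history$date - t0_date) / DAYS_PER_YEAR
  in_win <- which(off >= 1.5 & off <= 3)
  if (length(in_win) == 0L) return(NULL)
  d <- abs(off[in_win] - 2)
  # earlier measurement wins on ties
  pick <- in_win[order(d, off[in_win])][1L]
  list(date = history$date[pick], edss = history$edss[pick],
       offset_years = off[pick])
}

#' Build labelled progression samples from visits and EDSS histories
#'
#' Each EDSS measurement date serves as a candidate baseline T0. A visit
#' pairs with a T0 if it occurred within one year before or after it, and
#' the pair yields a sample if the patient has a follow-up EDSS between
#' 1.5 and 3 years after T0 (chosen by [select_t1()]). Visits without
#' two-year follow-up are discarded. When several baselines qualify for
#' one visit, identical (visit, T1) pairs are deduplicated and the
#' baseline closest to the visit date is kept, so each visit contributes
#' at most one sample.
#'
#' @param visits Visit table (`visit_id`, `patient_id`, `date`).
#' @param edss_history Table (`patient_id`, `date`, `edss`).
#' @return Data frame of samples: `visit_id`, `patient_id`, `t0_date`,
#'   `t1_date`, `edss_t0`, `edss_t1`, `target`.
#' @export
build_samples <- function(visits, edss_history) {
  out <- vector("list", nrow(visits))
  for (i in seq_len(nrow(visits))) {
    pid <- visits$patient_id[i]
    vdate <- visits$date[i]
    hist <- edss_history[edss_history$patient_id == pid, , drop = FALSE]
    if (nrow(hist) == 0L) next
    hist <- hist[order(hist$date), , drop = FALSE]
    t0_off <- abs(as.numeric(hist$date - vdate)) / DAYS_PER_YEAR
    cand <- which(t0_off <= 1)
    if (length(cand) == 0L) next
    rows <- list()
    for (j in cand[order(t0_off[cand])]) {
      t1 <- select_t1(hist, hist$date[j])
      if (is.null(t1)) next
      rows[[length(rows) + 1L]] <- data.frame(
        visit_id = visits$visit_id[i], patient_id = pid,
        t0_date = hist$date[j], t1_date = t1$date,
        edss_t0 = hist$edss[j], edss_t1 = t1$edss,
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) next
    rows <- do.call(rbind, rows)
    rows <- rows[!duplicated(rows[, c("visit_id", "t1_date")]), , drop = FALSE]
    # keep the baseline closest to the visit date (first row: cand is
    # iterated in order of |T0 - visit date|)
    out[[i]] <- rows[1L, , drop = FALSE]
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(visit_id = character(), patient_id = character(),
                      t0_date = as.Date(character()),
                      t1_date = as.Date(character()),
                      edss_t0 = numeric(), edss_t1 = numeric(),
                      stringsAsFactors = FALSE)
  }
  out$target <- if (nrow(out)) progression_label(out$edss_t0, out$edss_t1) else integer()
  rownames(out) <- NULL
  out
}
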