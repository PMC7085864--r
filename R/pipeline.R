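# Ties the stages together: from a raw cohort to aligned per-anatomy
# feature tables with labels and grouping keys.

#' Prepare a cohort for model fitting and evaluation
#'
#' Runs preprocessing (unless already applied), constructs the labelled
#' progression samples, extracts and normalizes the time-series feature
#' catalog, sums left and right sides, and assembles the per-anatomy
#' literature covariates (left and right annotated latency, EDSS at T0,
#' age). Rows of all returned tables are aligned: one row per labelled
#' visit.
#'
#' @param cohort An [mep_cohort].
#' @param facilitation_threshold Passed to [preprocess_cohort()].
#' @return A list: `ts` (named list of per-anatomy normalized TS feature
#'   matrices), `lit` (per-anatomy literature covariate matrices), `y`
#'   (targets), `groups` (patient ids), `visit_ids`, `samples` (the
#'   labelled sample table), and `discarded` (dropped feature columns).
#' @export
prepare_cohort <- function(cohort,
                           facilitation_threshold = FACILITATION_THRESHOLD_DEFAULT) {
  stopifnot(inherits(cohort, "mep_cohort"))
  if (!isTRUE(attr(cohort, "preprocessed"))) {
    cohort <- preprocess_cohort(cohort,
                                facilitation_threshold = facilitation_threshold)
  }
  samp <- build_samples(cohort$visits, cohort$edss_history)
  if (nrow(samp) == 0L) stop("no labelled samples in this cohort",
                             call. = FALSE)
  raw <- extract_features(cohort)

  visits <- cohort$visits[match(samp$visit_id, cohort$visits$visit_id), ,
                          drop = FALSE]
  anatomies <- c("APB", "AH")
  # the hands and feet pipelines run separately: normalize per anatomy
  discarded <- list()
  ts <- lapply(anatomies, function(an) {
    rows <- raw$keys$anatomy == an
    m <- feature_matrix(raw$values[rows, , drop = FALSE],
                        raw$keys[rows, , drop = FALSE])
    summed <- sum_left_right(robust_sigmoid_normalize(m))
    discarded[[an]] <<- summed$discarded
    v <- summed$values
    rownames(v) <- summed$keys$visit_id
    v[samp$visit_id, , drop = FALSE]
  })
  names(ts) <- anatomies
  lit <- list(
    APB = cbind(latency_l = visits$latency_apb_l_ms,
                latency_r = visits$latency_apb_r_ms,
                edss_t0 = samp$edss_t0,
                age = visits$age_years),
    AH = cbind(latency_l = visits$latency_ah_l_ms,
               latency_r = visits$latency_ah_r_ms,
               edss_t0 = samp$edss_t0,
               age = visits$age_years))
  lit <- lapply(lit, function(m) {
    rownames(m) <- samp$visit_id
    m
  })
  list(ts = ts, lit = lit, y = samp$target, groups = samp$patient_id,
       visit_ids = samp$visit_id, samples = samp,
       discarded = discarded,
       filter_log = attr(cohort, "filter_log"))
}
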