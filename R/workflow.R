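# Runnable surface: configuration, table I/O with schema validation, and
# the staged pipeline driver.

RECORDINGS_SCHEMA <- c("patient_id", "visit_id", "anatomy", "side",
                       "excitation_pct", "sampling_rate_hz", "sample_idx",
                       "value_mv")
VISITS_SCHEMA <- c("visit_id", "patient_id", "date", "age_years", "sex",
                   "ms_type", "edss", "latency_apb_l_ms", "latency_apb_r_ms",
                   "latency_ah_l_ms", "latency_ah_r_ms")
EDSS_SCHEMA <- c("patient_id", "date", "edss")

check_schema <- function(df, required, file) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema violation in '%s': missing column(s) %s", file,
                 paste(sprintf("'%s'", missing_cols), collapse = ", ")),
         call. = FALSE)
  }
  invisible(df)
}

#' Write a cohort to plain-text tables
#'
#' Writes `visits.csv`, `recordings.csv` (long format: one row per
#' sample), `edss_history.csv` and, when ground truth is present, a
#' `ground_truth.json` sidecar. Dates are ISO-8601. The long recording
#' format is intended for interchange of small cohorts; large cohorts
#' should be regenerated from their seed instead.
#'
#' @param cohort An [mep_cohort].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$visits[, setdiff(names(cohort$visits), "severity")],
                   file.path(dir, "visits.csv"), row.names = FALSE)
  utils::write.csv(cohort$edss_history, file.path(dir, "edss_history.csv"),
                   row.names = FALSE)
  rec <- cohort$recordings
  long <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    v <- cohort$samples[[rec$recording_id[i]]]
    data.frame(patient_id = rec$patient_id[i], visit_id = rec$visit_id[i],
               anatomy = rec$anatomy[i], side = rec$side[i],
               excitation_pct = rec$excitation_pct[i],
               sampling_rate_hz = rec$sampling_rate_hz[i],
               sample_idx = seq_along(v) - 1L, value_mv = v,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, file.path(dir, "recordings.csv"), row.names = FALSE)
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    jsonlite::write_json(
      list(coupling = as.list(gt$coupling),
           nonlinear_coupling = gt$nonlinear_coupling,
           intercept = gt$intercept,
           linear_predictor = as.list(gt$linear_predictor),
           label = as.list(gt$label)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort from plain-text tables
#'
#' Inverse of [write_cohort_csv()]; validates the table schemas and
#' reports the offending file and column on violation.
#'
#' @param dir Directory holding `visits.csv`, `recordings.csv` and
#'   `edss_history.csv`.
#' @return An [mep_cohort] (without ground truth).
#' @export
read_cohort_csv <- function(dir) {
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            stringsAsFactors = FALSE)
  check_schema(visits, VISITS_SCHEMA, file.path(dir, "visits.csv"))
  visits$date <- as.Date(visits$date)
  edss <- utils::read.csv(file.path(dir, "edss_history.csv"),
                          stringsAsFactors = FALSE)
  check_schema(edss, EDSS_SCHEMA, file.path(dir, "edss_history.csv"))
  edss$date <- as.Date(edss$date)
  long <- utils::read.csv(file.path(dir, "recordings.csv"),
                          stringsAsFactors = FALSE)
  check_schema(long, RECORDINGS_SCHEMA, file.path(dir, "recordings.csv"))
  key <- paste(long$visit_id, long$anatomy, long$side, long$excitation_pct,
               sep = "|")
  idx <- split(seq_len(nrow(long)), key)
  samples <- list(); meta <- list()
  for (k in names(idx)) {
    rows <- idx[[k]][order(long$sample_idx[idx[[k]]])]
    rid <- sprintf("R%06d", length(samples) + 1L)
    samples[[rid]] <- long$value_mv[rows]
    i <- rows[1L]
    meta[[length(meta) + 1L]] <- data.frame(
      recording_id = rid, visit_id = long$visit_id[i],
      patient_id = long$patient_id[i], anatomy = long$anatomy[i],
      side = long$side[i], excitation_pct = long$excitation_pct[i],
      sampling_rate_hz = long$sampling_rate_hz[i],
      n_samples = length(rows), stringsAsFactors = FALSE)
  }
  structure(list(visits = visits, recordings = do.call(rbind, meta),
                 samples = samples, edss_history = edss,
                 ground_truth = NULL, config = NULL),
            class = "mep_cohort")
}

#' Pipeline run configuration
#'
#' Collects every stage parameter with its documented default. Can be
#' loaded from a YAML file with [read_run_config()].
#'
#' @param cohort Arguments for [cohort_config()] (a list).
#' @param facilitation_threshold See [detect_facilitation()].
#' @param mi_fraction,cluster_cutoff,boruta Selection-cascade settings.
#' @param classifier `"rf"` or `"lr"`.
#' @param train_fractions,n_outer,n_inner,n_max Evaluation settings.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = list(),
                       facilitation_threshold = FACILITATION_THRESHOLD_DEFAULT,
                       mi_fraction = 0.10, cluster_cutoff = 0.1,
                       boruta = list(n_trees = 100L, max_iter = 100L,
                                     alpha = 0.05),
                       classifier = "rf",
                       train_fractions = c(0.2, 0.3, 0.5, 0.8),
                       n_outer = 20L, n_inner = 5L, n_max = 6L,
                       seed = 1L) {
  structure(list(cohort = cohort,
                 facilitation_threshold = facilitation_threshold,
                 mi_fraction = mi_fraction, cluster_cutoff = cluster_cutoff,
                 boruta = boruta, classifier = classifier,
                 train_fractions = train_fractions, n_outer = n_outer,
                 n_inner = n_inner, n_max = n_max, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

config_hash <- function(config) {
  s <- jsonlite::serializeJSON(unclass(config))
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 536870909  # polynomial hash < 2^30
  sprintf("%08x", as.integer(h))
}

#' Run the pipeline stages end to end
#'
#' Executes `simulate` (synthetic cohort), `prepare` (preprocessing,
#' labelling, feature extraction) and `evaluate` (the grouped-split
#' experiment) in dependency order, writing artifacts stamped with the
#' configuration hash and seed. Row counts after every filter are
#' reported through the filter log so the cohort accounting chain stays
#' auditable.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("simulate", "prepare", "evaluate")`.
#' @param out_dir Output directory for JSON/CSV artifacts, or `NULL` to
#'   skip writing.
#' @param quiet Suppress progress messages.
#' @return A list with the cohort, the prepared data, the experiment
#'   result, and the filter log.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "prepare", "evaluate"),
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, c("simulate", "prepare", "evaluate"),
                      several.ok = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- config_hash(config)
  out <- list(config = config, config_hash = hash)

  say("[simulate] generating cohort (seed %d)", config$seed)
  cc <- do.call(cohort_config, c(config$cohort,
                                 if (is.null(config$cohort$seed))
                                   list(seed = config$seed)))
  out$cohort <- generate_cohort(cc)
  say("[simulate] %d visits, %d recordings", nrow(out$cohort$visits),
      nrow(out$cohort$recordings))

  if (!any(c("prepare", "evaluate") %in% stages)) return(invisible(out))
  say("[prepare] preprocessing, labelling, feature extraction")
  out$prepared <- prepare_cohort(
    out$cohort, facilitation_threshold = config$facilitation_threshold)
  fl <- out$prepared$filter_log
  if (!quiet && !is.null(fl)) {
    for (i in seq_len(nrow(fl))) {
      say("[prepare] %s: %d -> %d (%s)", fl$stage[i], fl$rows_before[i],
          fl$rows_after[i], fl$reason[i])
    }
  }
  say("[prepare] %d labelled samples, prevalence %.3f",
      length(out$prepared$y), mean(out$prepared$y))

  if ("evaluate" %in% stages) {
    say("[evaluate] %s, fractions %s, %d x %d splits", config$classifier,
        paste(config$train_fractions, collapse = "/"), config$n_outer,
        config$n_inner)
    out$experiment <- run_experiment(
      out$prepared, train_fractions = config$train_fractions,
      n_outer = config$n_outer, n_inner = config$n_inner,
      n_max = config$n_max, kind = config$classifier,
      mi_fraction = config$mi_fraction,
      cluster_cutoff = config$cluster_cutoff,
      n_trees = config$boruta$n_trees,
      boruta_max_iter = config$boruta$max_iter,
      alpha = config$boruta$alpha, seed = config$seed)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- list(config_hash = hash, seed = config$seed)
    if (!is.null(out$prepared)) {
      utils::write.csv(out$prepared$samples,
                       file.path(out_dir, "samples.csv"), row.names = FALSE)
      utils::write.csv(out$prepared$filter_log,
                       file.path(out_dir, "filter_log.csv"),
                       row.names = FALSE)
    }
    if (!is.null(out$experiment)) {
      jsonlite::write_json(
        c(stamp, list(records = out$experiment$records,
                      aggregates = out$experiment$aggregates)),
        file.path(out_dir, "evaluation.json"), auto_unbox = TRUE,
        digits = NA, dataframe = "rows")
      utils::write.csv(out$experiment$aggregates,
                       file.path(out_dir, "table_results.csv"),
                       row.names = FALSE)
    }
  }
  invisible(out)
}

#' Serialize a selection report
#'
#' Writes the cascade's outcome as JSON (MI scores, survivors, Boruta
#' decisions and importances) and the ranked feature list as plain text,
#' one feature per line.
#'
#' @param report A `selection_report` from [select_features()].
#' @param path Output path for the JSON; the ranked list goes to the
#'   same path with extension `.ranked.txt`.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  jsonlite::write_json(
    list(mi_scores = as.list(report$mi_scores),
         preselected = report$preselected,
         cluster_survivors = report$cluster_survivors,
         boruta = list(decision = as.list(report$boruta$decision),
                       hits = as.list(report$boruta$hits),
                       rounds = as.list(report$boruta$rounds),
                       mean_importance = as.list(report$boruta$mean_importance)),
         ranked_ts = report$ranked_ts,
         literature = report$literature),
    path, auto_unbox = TRUE, digits = NA)
  writeLines(report$ranked_ts,
             paste0(sub("\\.json$", "", path), ".ranked.txt"))
  invisible(path)
}

#' Persist the metadata of a fitted progression model
#'
#' Writes the audit trail of an [fit_progression()] bundle: classifier
#' kind, per-anatomy feature lists, training size and prevalence, and
#' seed.
#'
#' @param model An `mep_model`.
#' @param path Output JSON path.
#' @param config_hash Optional configuration hash to stamp.
#' @return `path`, invisibly.
#' @export
write_model_metadata <- function(model, path, config_hash = NULL) {
  stopifnot(inherits(model, "mep_model"))
  jsonlite::write_json(
    list(kind = model$kind,
         features = model$features,
         lit_features = model$lit_features,
         ts_features = model$ts_features,
         n_train = model$n, prevalence = model$prevalence,
         seed = model$seed, config_hash = config_hash),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
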