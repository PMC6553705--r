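# End-to-end orchestration: simulate or ingest, build networks and feature
# tables, run the correlation analysis, and produce the prediction report.

#' Compare feature sets for one wellness attribute
#'
#' Runs [predict_wellness()] for the `baseline`, `network_only` and `full`
#' feature sets plus the uniform-random baseline, all on the same split
#' seed, and assembles the improvement table via [make_prediction_table()].
#'
#' @inheritParams predict_wellness
#' @param reps Monte-Carlo repetitions of the random baseline.
#' @return list: `reports` (per feature set), `random`, `table`
#'   (the improvement table).
#' @export
compare_feature_sets <- function(table, attribute, seed = 1L,
                                 grids = classifier_grids(), frac = 0.75,
                                 unit = "participant", weight_mode = "scalar",
                                 classifiers = CLASSIFIER_ORDER,
                                 n_folds = 5L, reps = 200L) {
  reports <- list()
  for (fs in c("baseline", "network_only", "full")) {
    reports[[fs]] <- predict_wellness(table, attribute, feature_set = fs,
                                      seed = seed, frac = frac, unit = unit,
                                      grids = grids, weight_mode = weight_mode,
                                      classifiers = classifiers, n_folds = n_folds)
  }
  K <- length(WELLNESS_RANGES[[attribute]])
  rand <- random_baseline(reports$full$test_labels, K, seed = seed, reps = reps)
  tbl <- make_prediction_table(rand, reports$baseline$f1, reports$network_only$f1,
                     reports$full$f1, K)
  list(reports = reports, random = rand, table = tbl, attribute = attribute)
}

#' Assemble the prediction report table
#'
#' Five rows in fixed order -- random baseline, gender + behavior,
#' network-only, full feature set, and the improvement row -- with the
#' overall (macro) F1 and the per-level F1 columns. The improvement row is
#' [relative_improvement()] of the baseline and full rows, column by
#' column.
#'
#' @param random output of [random_baseline()].
#' @param f1_baseline,f1_network,f1_full test reports ([f1_report()]) of
#'   the three feature sets.
#' @param K number of classes.
#' @return `data.table` with columns model, overall, level1..levelK.
#' @export
make_prediction_table <- function(random, f1_baseline, f1_network, f1_full, K) {
  if (is.null(random) || is.null(f1_baseline) || is.null(f1_network) ||
      is.null(f1_full)) {
    stop("all four reports are required", call. = FALSE)
  }
  level_cols <- paste0("level", seq_len(K))
  row <- function(model, overall, per_level) {
    out <- data.table::data.table(model = model, overall = overall)
    for (i in seq_len(K)) out[[level_cols[i]]] <- per_level[i]
    out
  }
  tbl <- data.table::rbindlist(list(
    row("random", random$macro_f1, random$per_class_f1),
    row("baseline", f1_baseline$macro_f1, f1_baseline$per_class$f1),
    row("network", f1_network$macro_f1, f1_network$per_class$f1),
    row("full", f1_full$macro_f1, f1_full$per_class$f1)
  ))
  imp <- suppressWarnings(vapply(c("overall", level_cols), function(col) {
    as.numeric(relative_improvement(tbl[model == "baseline"][[col]],
                                    tbl[model == "full"][[col]]))
  }, numeric(1)))
  imp_row <- data.table::data.table(model = "improvement", overall = imp[["overall"]])
  for (i in seq_len(K)) imp_row[[level_cols[i]]] <- imp[[level_cols[i]]]
  data.table::rbindlist(list(tbl, imp_row))
}

#' Run the full pipeline
#'
#' Either simulates a synthetic study (`sim_config` given) or ingests the
#' three CSVs (`events_path`, `minutes_path`, `survey_path` with a
#' `study`), then builds weekly networks and behavioral features, runs the
#' cohort and per-person correlation analysis with high/low tests, and --
#' optionally -- the prediction stage for each requested attribute. All
#' stage tables and a JSON run-metadata file are written under `out_dir`
#' when given.
#'
#' @param sim_config a [generator_config()], or `NULL` to ingest files.
#' @param events_path,minutes_path,survey_path input CSVs (ignored when
#'   `sim_config` is given).
#' @param study a [study_config()] (required for file input).
#' @param out_dir optional output directory.
#' @param attributes wellness attributes to predict (`character(0)` skips
#'   the prediction stage).
#' @param tau thresholds for pair counting (default `c(0.5, 0.7)`).
#' @param grids classifier grids for the prediction stage.
#' @param predict_seed seed for the prediction stage (defaults to the study
#'   seed).
#' @return list with `behavior`, `structure`, `features`, `pair_matrix`,
#'   `pair_counts`, `person_counts`, `high_low`, `anova`, `predictions`,
#'   `study`.
#' @export
run_pipeline <- function(sim_config = NULL, events_path = NULL,
                         minutes_path = NULL, survey_path = NULL,
                         study = NULL, out_dir = NULL,
                         attributes = character(0), tau = c(0.5, 0.7),
                         grids = classifier_grids(fast = TRUE),
                         predict_seed = NULL) {
  if (is.null(sim_config)) {
    if (is.null(events_path) || is.null(minutes_path) || is.null(survey_path)) {
      stop("provide either `sim_config` or all three input paths", call. = FALSE)
    }
    if (is.null(study)) stop("`study` config required for file input", call. = FALSE)
    for (p in c(events_path, minutes_path, survey_path)) {
      if (!file.exists(p)) stop(sprintf("input file missing: %s", p), call. = FALSE)
    }
    events <- read_comm_events(events_path, study)
    minutes <- read_minute_records(minutes_path, study)
    survey <- read_survey(survey_path)
  } else {
    sim <- simulate_study(sim_config)
    events <- sim$events
    minutes <- sim$minutes
    survey <- sim$survey
    study <- sim$study
  }

  structure_tbl <- structural_feature_table(events, study)
  behavior_tbl <- behavior_feature_table(minutes, study)
  features <- feature_table(behavior_tbl, structure_tbl, survey)

  pair_matrix <- cohort_pair_matrix(behavior_tbl, structure_tbl)
  pair_counts <- setNames(
    vapply(tau, function(t) count_pairs(pair_matrix, t), numeric(1)),
    paste0("tau_", tau))
  person_counts <- per_person_counts(behavior_tbl, structure_tbl)
  high_low <- high_low_tests(behavior_tbl, structure_tbl)
  anova_tbl <- tryCatch(anova_by_level(behavior_tbl, survey),
                        error = function(e) NULL)

  predictions <- list()
  for (attr_name in attributes) {
    predictions[[attr_name]] <- compare_feature_sets(
      features, attr_name, seed = predict_seed %||% study$seed, grids = grids)
  }

  result <- list(behavior = behavior_tbl, structure = structure_tbl,
                 features = features, pair_matrix = pair_matrix,
                 pair_counts = pair_counts, person_counts = person_counts,
                 high_low = high_low, anova = anova_tbl,
                 predictions = predictions, study = study)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(behavior_tbl, file.path(out_dir, "behavior_features.csv"))
    data.table::fwrite(structure_tbl, file.path(out_dir, "structure_features.csv"))
    data.table::fwrite(features, file.path(out_dir, "feature_table.csv"))
    data.table::fwrite(pair_matrix, file.path(out_dir, "pair_correlations.csv"))
    data.table::fwrite(person_counts$per_pair, file.path(out_dir, "person_counts_per_pair.csv"))
    data.table::fwrite(person_counts$per_behavior, file.path(out_dir, "person_counts_per_behavior.csv"))
    data.table::fwrite(high_low, file.path(out_dir, "high_low_tests.csv"))
    if (!is.null(anova_tbl)) {
      data.table::fwrite(anova_tbl, file.path(out_dir, "anova_by_level.csv"))
    }
    for (attr_name in names(predictions)) {
      data.table::fwrite(predictions[[attr_name]]$table,
                         file.path(out_dir, sprintf("prediction_%s.csv", attr_name)))
    }
    meta <- list(
      seed = study$seed,
      study_start = format(study$study_start), n_weeks = study$n_weeks,
      n_roster = length(study$roster),
      wear_threshold_min = study$wear_threshold_min,
      edge_min_events = study$edge_min_events,
      n_events = nrow(events), n_minutes = nrow(minutes),
      pair_counts = as.list(pair_counts),
      n_significant_high_low = sum(high_low$significant),
      r_version = R.version.string
    )
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
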