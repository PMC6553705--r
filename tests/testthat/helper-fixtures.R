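# Shared fixtures: a small study configuration, CSV writers for reader
# tests, and a memoized default synthetic study so expensive stages are
# simulated once per test run.

tiny_config <- function(roster = c("A", "B", "C"), n_weeks = 4L, ...) {
  study_config("2016-08-01", roster = roster, n_weeks = n_weeks, ...)
}

write_csv_lines <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

events_csv <- function(rows) {
  write_csv_lines(c("timestamp,source,target,channel,duration_s,answered", rows))
}

minutes_csv <- function(rows) {
  write_csv_lines(c("participant,timestamp,heart_rate,steps,state", rows))
}

survey_csv <- function(rows) {
  write_csv_lines(c("participant,gender,stress,happiness,positive_attitude,health", rows))
}

# Minute rows for one participant-day: `worn` worn minutes from midnight,
# constant heart rate and steps, one state.
day_minutes <- function(participant, date, worn, hr = 70, steps = 5,
                        state = "sedentary") {
  ts <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + 60 * (seq_len(worn) - 1)
  data.table::data.table(participant = participant, timestamp = ts,
                         heart_rate = hr, steps = as.integer(steps),
                         state = state)
}

# Small, fast generator settings for pipeline-level tests; any
# generator_config argument can be overridden.
small_gen_config <- function(seed = 11L, ...) {
  args <- list(n_participants = 12L, n_external = 24L, n_weeks = 6L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

# Default-condition synthetic study, simulated once per test session.
.sim_cache <- new.env(parent = emptyenv())
cached_default_run <- function() {
  if (is.null(.sim_cache$run)) {
    sim <- simulate_study(generator_config(seed = 20160801L))
    bt <- behavior_feature_table(sim$minutes, sim$study)
    st <- structural_feature_table(sim$events, sim$study)
    sim$minutes <- NULL   # ~12M rows; only the derived tables are needed
    .sim_cache$run <- list(sim = sim, behavior = bt, structure = st,
                           features = feature_table(bt, st, sim$survey))
  }
  .sim_cache$run
}
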