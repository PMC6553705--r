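# Canonical data types, CSV readers/writers and the week-indexing convention
# shared by every stage of the pipeline.

ACTIVITY_STATES <- c("sedentary", "lightly", "fairly", "very")

# Likert ranges of the four wellness attributes (ordinal class labels).
WELLNESS_RANGES <- list(
  stress = 1:4, happiness = 1:4, positive_attitude = 1:5, health = 1:4
)

#' Wellness attributes handled by the pipeline
#' @return named list mapping attribute name to its ordinal range.
#' @export
wellness_attributes <- function() WELLNESS_RANGES

#' Study configuration
#'
#' Fixes the study window, the participant roster, and the two
#' preprocessing thresholds: the daily wear-time rule (a participant-day is
#' kept only when the device was worn at least `wear_threshold_min` minutes,
#' default 1140 = 19 of 24 hours) and the spurious-edge filter (a
#' communication edge is kept only when the pair exchanged at least
#' `edge_min_events` calls or texts over the whole window, default 3).
#'
#' @param study_start first day of the study window (`Date` or
#'   "YYYY-MM-DD"). Weeks are consecutive 7-day bins anchored here.
#' @param roster character vector of enrolled participant ids. Any id not in
#'   the roster is treated as an external contact.
#' @param n_weeks number of weekly time points (default 22).
#' @param wear_threshold_min minimum worn minutes for a valid day (default 1140).
#' @param edge_min_events minimum total events for a retained edge (default 3).
#' @param seed integer root seed for any randomness downstream.
#' @return object of class `study_config`.
#' @export
study_config <- function(study_start, roster, n_weeks = 22L,
                         wear_threshold_min = 1140L, edge_min_events = 3L,
                         seed = 1L) {
  study_start <- as.Date(study_start)
  if (is.na(study_start)) stop("`study_start` must be a valid date", call. = FALSE)
  assert_scalar_number(n_weeks, "n_weeks", lower = 1)
  assert_scalar_number(wear_threshold_min, "wear_threshold_min", 0, 1440)
  assert_scalar_number(edge_min_events, "edge_min_events", lower = 0)
  if (length(roster) == 0) stop("`roster` must be non-empty", call. = FALSE)
  structure(list(
    study_start = study_start,
    n_weeks = as.integer(n_weeks),
    roster = as.character(unique(roster)),
    wear_threshold_min = as.integer(wear_threshold_min),
    edge_min_events = as.integer(edge_min_events),
    seed = as.integer(seed)
  ), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  window   :", format(x$study_start), "+", x$n_weeks, "weeks\n")
  cat("  roster   :", length(x$roster), "participants\n")
  cat("  wear rule: >=", x$wear_threshold_min, "min/day\n")
  cat("  edge rule: >=", x$edge_min_events, "events/window\n")
  invisible(x)
}

#' Assign a timestamp to a week index
#'
#' Weeks are consecutive 7-day bins anchored at `study_start`:
#' `floor(days_since_start / 7)`. Indices at or beyond `n_weeks` are
#' returned as computed but lie outside the analysis window (see
#' [in_study_window()]).
#'
#' @param timestamp `POSIXct`/`Date` vector (or ISO-8601 strings).
#' @param config a [study_config()].
#' @return integer vector of 0-based week indices.
#' @export
assign_week <- function(timestamp, config) {
  ts <- as_utc_time(timestamp)
  days <- as.numeric(difftime(ts, as.POSIXct(config$study_start, tz = "UTC"),
                              units = "days"))
  if (any(days < 0, na.rm = TRUE)) {
    stop("timestamp precedes study_start", call. = FALSE)
  }
  as.integer(floor(days / 7))
}

#' Is a timestamp inside the configured study window?
#' @inheritParams assign_week
#' @return logical vector.
#' @export
in_study_window <- function(timestamp, config) {
  ts <- as_utc_time(timestamp)
  start <- as.POSIXct(config$study_start, tz = "UTC")
  days <- as.numeric(difftime(ts, start, units = "days"))
  !is.na(days) & days >= 0 & floor(days / 7) < config$n_weeks
}

as_utc_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "Date")) return(as.POSIXct(x, tz = "UTC"))
  x <- as.character(x)
  out <- .POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  # per-element coalescing parse, most specific format first (a bare
  # all-formats as.POSIXct would let %Y-%m-%d truncate full timestamps)
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- which(is.na(out) & !is.na(x) & nzchar(x))
    if (!length(todo)) break
    cand <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
    hit <- !is.na(cand)
    out[todo[hit]] <- cand[hit]
  }
  out
}

require_columns <- function(dt, cols, path) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

parse_times_or_die <- function(x, path) {
  if (inherits(x, "POSIXct")) return(x)   # fread already parsed ISO-8601 (UTC)
  x <- as.character(x)
  ts <- as_utc_time(x)
  bad <- which(is.na(ts) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop(sprintf("%s: malformed timestamp at data line %d: '%s'", path,
                 bad[1], x[bad[1]]), call. = FALSE)
  }
  ts
}

#' Read a communication event log
#'
#' Expects a headed CSV with columns `timestamp`, `source`, `target`,
#' `channel` (call|text) and optional `duration_s`, `answered`. Rows outside
#' the study window are dropped and counted; self-loop rows (source ==
#' target) are rejected and counted. Counts are attached as the
#' `"ingest_log"` attribute.
#'
#' @param path CSV file path.
#' @param config a [study_config()].
#' @return `data.table` of events (timestamp, source, target, channel,
#'   duration_s, answered, week).
#' @export
read_comm_events <- function(path, config) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = c("source", "target")))
  require_columns(dt, c("timestamp", "source", "target", "channel"), path)
  if (nrow(dt) == 0) {
    out <- empty_events()
    attr(out, "ingest_log") <- list(read = 0L, out_of_window = 0L, self_loops = 0L)
    return(out)
  }
  dt[, timestamp := parse_times_or_die(timestamp, path)]
  bad_channel <- which(!dt$channel %in% c("call", "text"))
  if (length(bad_channel)) {
    stop(sprintf("%s: invalid channel at data line %d: '%s'", path,
                 bad_channel[1], dt$channel[bad_channel[1]]), call. = FALSE)
  }
  if (!"duration_s" %in% names(dt)) dt[, duration_s := NA_real_]
  if (!"answered" %in% names(dt)) dt[, answered := NA]
  dt[, duration_s := as.numeric(duration_s)]
  dt[, answered := as.logical(answered)]
  if (any(dt$duration_s < 0, na.rm = TRUE)) {
    stop(sprintf("%s: negative duration_s", path), call. = FALSE)
  }

  self_loops <- dt$source == dt$target
  in_window <- in_study_window(dt$timestamp, config)
  keep <- !self_loops & in_window
  log <- list(read = nrow(dt),
              out_of_window = sum(!in_window),
              self_loops = sum(self_loops & in_window))
  if (log$self_loops > 0 || log$out_of_window > 0) {
    message(sprintf("read_comm_events: dropped %d out-of-window and %d self-loop row(s)",
                    log$out_of_window, log$self_loops))
  }
  out <- dt[keep]
  out[, week := assign_week(timestamp, config)]
  data.table::setcolorder(out, c("timestamp", "source", "target", "channel",
                                 "duration_s", "answered", "week"))
  attr(out, "ingest_log") <- log
  out[]
}

empty_events <- function() {
  data.table::data.table(
    timestamp = as.POSIXct(character(), tz = "UTC"), source = character(),
    target = character(), channel = character(), duration_s = numeric(),
    answered = logical(), week = integer()
  )
}

#' Read minute-level wearable records
#'
#' Expects a headed CSV with columns `participant`, `timestamp`,
#' `heart_rate` (bpm, blank for non-wear minutes), `steps`, `state`
#' (sedentary|lightly|fairly|very, blank allowed). Duplicate
#' participant-minutes are resolved keep-first with a warning; rows outside
#' the study window are dropped with a count in the `"ingest_log"` attribute.
#'
#' @inheritParams read_comm_events
#' @return `data.table` of minute records (participant, timestamp,
#'   heart_rate, steps, state, week).
#' @export
read_minute_records <- function(path, config) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "participant"))
  require_columns(dt, c("participant", "timestamp", "heart_rate", "steps", "state"), path)
  if (nrow(dt) == 0) {
    return(empty_minutes())
  }
  dt[, timestamp := parse_times_or_die(timestamp, path)]
  dt[, heart_rate := as.numeric(heart_rate)]
  dt[, steps := as.integer(steps)]
  dt[, state := as.character(state)]
  dt[state == "", state := NA_character_]
  bad_state <- which(!is.na(dt$state) & !dt$state %in% ACTIVITY_STATES)
  if (length(bad_state)) {
    stop(sprintf("%s: invalid activity state at data line %d: '%s'", path,
                 bad_state[1], dt$state[bad_state[1]]), call. = FALSE)
  }
  if (any(dt$heart_rate <= 0, na.rm = TRUE)) {
    stop(sprintf("%s: non-positive heart_rate", path), call. = FALSE)
  }
  if (any(dt$steps < 0, na.rm = TRUE)) {
    stop(sprintf("%s: negative steps", path), call. = FALSE)
  }
  in_window <- in_study_window(dt$timestamp, config)
  dt <- dt[in_window]
  dup <- duplicated(dt, by = c("participant", "timestamp"))
  if (any(dup)) {
    warning(sprintf("read_minute_records: %d duplicate participant-minute row(s); keeping first",
                    sum(dup)), call. = FALSE)
    dt <- dt[!dup]
  }
  dt[, week := assign_week(timestamp, config)]
  attr(dt, "ingest_log") <- list(out_of_window = sum(!in_window),
                                 duplicates = sum(dup))
  dt[]
}

empty_minutes <- function() {
  data.table::data.table(
    participant = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    heart_rate = numeric(), steps = integer(), state = character(),
    week = integer()
  )
}

#' Read the wellness survey table
#'
#' Expects a headed CSV with columns `participant`, `gender`
#' (male|female|unreported), and ordinal columns `stress`, `happiness`,
#' `positive_attitude`, `health`. Ordinal values are validated against
#' their Likert ranges (1-4 for stress/happiness/health, 1-5 for positive
#' attitude); blanks are allowed and treated as missing.
#'
#' @param path CSV file path.
#' @return `data.table`, one row per participant.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "participant"))
  require_columns(dt, c("participant", "gender", names(WELLNESS_RANGES)), path)
  if (nrow(dt) == 0) return(dt)
  bad_gender <- which(!dt$gender %in% c("male", "female", "unreported"))
  if (length(bad_gender)) {
    stop(sprintf("%s: invalid gender at data line %d: '%s'", path,
                 bad_gender[1], dt$gender[bad_gender[1]]), call. = FALSE)
  }
  for (attr_name in names(WELLNESS_RANGES)) {
    vals <- suppressWarnings(as.integer(dt[[attr_name]]))
    rng <- WELLNESS_RANGES[[attr_name]]
    bad <- which(!is.na(vals) & !vals %in% rng)
    if (length(bad)) {
      stop(sprintf("%s: %s=%s at data line %d outside range %d-%d", path,
                   attr_name, dt[[attr_name]][bad[1]], bad[1], min(rng), max(rng)),
           call. = FALSE)
    }
    data.table::set(dt, j = attr_name, value = vals)
  }
  if (anyDuplicated(dt$participant)) {
    warning("read_survey: duplicate participant rows; keeping first", call. = FALSE)
    dt <- dt[!duplicated(participant)]
  }
  dt[]
}

#' Write the three standard tables as CSV
#'
#' Inverse of the readers: [read_comm_events()], [read_minute_records()] and
#' [read_survey()] reproduce the written content exactly.
#'
#' @param x a `data.table` from the corresponding reader or generator.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comm_events <- function(x, path) {
  out <- data.table::as.data.table(x)
  out <- out[, c("timestamp", "source", "target", "channel", "duration_s", "answered")]
  out[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_comm_events
#' @export
write_minute_records <- function(x, path) {
  out <- data.table::as.data.table(x)
  out <- out[, c("participant", "timestamp", "heart_rate", "steps", "state")]
  out[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_comm_events
#' @export
write_survey <- function(x, path) {
  out <- data.table::as.data.table(x)
  out <- out[, c("participant", "gender", names(WELLNESS_RANGES)), with = FALSE]
  data.table::fwrite(out, path)
  invisible(path)
}
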