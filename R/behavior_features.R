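# Daily wear-time rule and the twelve weekly behavioral features:
# heart-rate mean and variance, daily-steps mean and sd, and mean and sd of
# daily minutes in each of the four activity states.

BEHAVIOR_FEATURES <- c("hr_mean", "hr_var", "steps_mean", "steps_sd",
                       "sed_mean", "sed_sd", "light_mean", "light_sd",
                       "fair_mean", "fair_sd", "very_mean", "very_sd")

#' Aggregate one participant-day of minute records
#'
#' A minute counts as worn iff its heart rate is non-missing (optical heart
#' rate as the wear proxy). The day is valid iff worn minutes reach the
#' configured threshold (default 1140 = 19 of 24 hours).
#'
#' @param minutes minute records of a single participant-day.
#' @param config a [study_config()].
#' @return one-row `data.table`: participant, date, worn_minutes,
#'   daily_steps, sed/light/fair/very minutes, hr_sum, hr_sumsq, hr_count,
#'   valid.
#' @export
daily_aggregate <- function(minutes, config) {
  dt <- data.table::as.data.table(minutes)
  if (length(unique(dt$participant)) > 1 ||
      length(unique(as.Date(dt$timestamp, tz = "UTC"))) > 1) {
    stop("daily_aggregate expects records of a single participant-day", call. = FALSE)
  }
  agg <- daily_aggregate_all(dt, config)
  agg[]
}

# Vectorized daily aggregation over the full minute stream.
daily_aggregate_all <- function(minutes, config) {
  dt <- data.table::as.data.table(minutes)
  if (nrow(dt) == 0) {
    return(data.table::data.table(
      participant = character(), date = as.Date(character()),
      worn_minutes = integer(), daily_steps = integer(),
      sed_min = integer(), light_min = integer(), fair_min = integer(),
      very_min = integer(), hr_sum = numeric(), hr_sumsq = numeric(),
      hr_count = integer(), valid = logical()
    ))
  }
  dt[, date := as.Date(timestamp, tz = "UTC")]
  # precompute flat columns so the grouped sums use data.table's fast path
  worn <- !is.na(dt$heart_rate)
  si <- data.table::chmatch(dt$state, ACTIVITY_STATES)
  work <- data.table::setDT(list(
    participant = dt$participant, date = dt$date,
    worn_minutes = as.integer(worn),
    daily_steps = data.table::fifelse(is.na(dt$steps), 0L, dt$steps),
    sed_min = as.integer(worn & !is.na(si) & si == 1L),
    light_min = as.integer(worn & !is.na(si) & si == 2L),
    fair_min = as.integer(worn & !is.na(si) & si == 3L),
    very_min = as.integer(worn & !is.na(si) & si == 4L),
    hr_sum = data.table::fifelse(worn, dt$heart_rate, 0),
    hr_sumsq = data.table::fifelse(worn, dt$heart_rate^2, 0),
    hr_count = as.integer(worn)
  ))
  agg <- work[, lapply(.SD, sum), by = .(participant, date)]
  agg[, valid := worn_minutes >= config$wear_threshold_min]
  agg[]
}

# sd over valid-day totals: sample (n-1) sd, 0 for a single day.
day_sd <- function(x) {
  if (length(x) <= 1) return(0)
  sd(x)
}

#' Weekly behavioral features for one participant-week
#'
#' Pools heart rate over all worn minutes of valid days (mean and
#' population variance of the minute series); daily steps and per-state
#' daily minutes are summarized as mean and sample (n-1) standard deviation
#' over valid days, with sd 0 by convention when only one valid day
#' remains. Invalid days (below the wear threshold) are excluded entirely.
#' With zero valid days the row is emitted with missing features.
#'
#' @param days `data.table` of day aggregates (one participant-week) from
#'   [daily_aggregate_all()].
#' @return one-row `data.table` with the 12 features and `n_valid_days`.
#' @export
weekly_behavior <- function(days) {
  dt <- data.table::as.data.table(days)
  v <- dt[valid == TRUE]
  n_valid <- nrow(v)
  if (n_valid == 0) {
    out <- data.table::as.data.table(
      setNames(as.list(rep(NA_real_, length(BEHAVIOR_FEATURES))), BEHAVIOR_FEATURES))
    out[, n_valid_days := 0L]
    return(out[])
  }
  hr_n <- sum(v$hr_count)
  hr_mean <- sum(v$hr_sum) / hr_n
  hr_var <- sum(v$hr_sumsq) / hr_n - hr_mean^2   # population variance of minutes
  data.table::data.table(
    hr_mean = hr_mean, hr_var = max(hr_var, 0),
    steps_mean = mean(v$daily_steps), steps_sd = day_sd(v$daily_steps),
    sed_mean = mean(v$sed_min), sed_sd = day_sd(v$sed_min),
    light_mean = mean(v$light_min), light_sd = day_sd(v$light_min),
    fair_mean = mean(v$fair_min), fair_sd = day_sd(v$fair_min),
    very_mean = mean(v$very_min), very_sd = day_sd(v$very_min),
    n_valid_days = n_valid
  )
}

#' Weekly behavioral feature table for the whole stream
#'
#' Applies [daily_aggregate_all()] and [weekly_behavior()] across the full
#' minute stream: one row per participant-week, including weeks with no
#' valid days (missing features, `n_valid_days = 0`) so the table is
#' rectangular over participants x weeks for every participant present in
#' the stream.
#'
#' @param minutes minute records table.
#' @param config a [study_config()].
#' @return `data.table` (participant, week, 12 features, n_valid_days).
#' @export
behavior_feature_table <- function(minutes, config) {
  days <- daily_aggregate_all(minutes, config)
  if (nrow(days) == 0) {
    return(data.table::data.table(participant = character(), week = integer()))
  }
  days[, week := assign_week(date, config)]
  days <- days[week >= 0 & week < config$n_weeks]
  grid <- data.table::CJ(participant = sort(unique(days$participant)),
                         week = seq_len(config$n_weeks) - 1L)
  # grouped form of weekly_behavior(), vectorized over all participant-weeks
  weekly <- days[valid == TRUE, .(
    hr_mean = sum(hr_sum) / sum(hr_count),
    hr_var = pmax(sum(hr_sumsq) / sum(hr_count) - (sum(hr_sum) / sum(hr_count))^2, 0),
    steps_mean = mean(daily_steps), steps_sd = sd(daily_steps),
    sed_mean = mean(sed_min), sed_sd = sd(sed_min),
    light_mean = mean(light_min), light_sd = sd(light_min),
    fair_mean = mean(fair_min), fair_sd = sd(fair_min),
    very_mean = mean(very_min), very_sd = sd(very_min),
    n_valid_days = .N
  ), by = .(participant, week)]
  sd_cols <- grep("_sd$", BEHAVIOR_FEATURES, value = TRUE)
  weekly[n_valid_days == 1L, (sd_cols) := 0]   # single-day sd convention
  out <- weekly[grid, on = c("participant", "week")]
  out[is.na(n_valid_days), n_valid_days := 0L]
  data.table::setorder(out, participant, week)
  out[]
}
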