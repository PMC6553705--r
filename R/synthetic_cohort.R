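# Synthetic-cohort simulator: event logs, wearable streams and survey labels
# with the statistical structure the downstream analysis assumes -- a shared
# smooth weekly factor couples communication activity and physical activity,
# and ordinal wellness labels derive from a latent score over behavioral and
# network propensities.

# Cumulative level proportions used to threshold the latent wellness score,
# emulating the skewed Likert marginals typical of college-cohort surveys
# (rare extreme-low levels, a dominant middle level).
LABEL_CUT_PROBS <- list(
  stress = c(0.045, 0.335, 0.75),
  happiness = c(0.12, 0.38, 0.82),
  positive_attitude = c(0.01, 0.08, 0.28, 0.77),
  health = c(0.02, 0.19, 0.81)
)

#' Synthetic-cohort generator configuration
#'
#' Parameters of the simulator. `coupling_rho` scales a shared smooth weekly
#' factor that jointly modulates communication rates and physical activity,
#' planting the cohort-level cross-correlations the analysis is designed to
#' detect (0 = no coupling). `label_beta_behavior` and `label_beta_network`
#' are effect sizes of the standardized fitness and sociability propensities
#' on the latent wellness score that is thresholded into ordinal labels;
#' `noise_sd` is the sd of the latent noise (and scales minute-level heart
#' rate noise).
#'
#' @param n_participants enrolled cohort size (default 60; the emulated
#'   study had 325).
#' @param n_external number of non-enrolled contacts (default 120).
#' @param n_weeks weekly time points (default 22).
#' @param coupling_rho shared weekly factor strength in `[0, 1]` (default 0.9).
#' @param label_beta_behavior,label_beta_network latent-scale effect sizes
#'   (defaults 0.8 and 1.2).
#' @param noise_sd latent noise sd, must be positive scale (default 1).
#' @param seed integer root seed; every generator derives named sub-streams
#'   from it.
#' @param study_start first study day (default "2016-08-01").
#' @param weekly_events_per_participant expected communication events per
#'   participant per week at coupling factor 1 (default 6).
#' @param low_wear_frac fraction of participant-days generated with too few
#'   worn minutes to pass the daily wear rule (default 0.1).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 60L, n_external = 120L,
                             n_weeks = 22L, coupling_rho = 0.9,
                             label_beta_behavior = 0.8,
                             label_beta_network = 1.2,
                             noise_sd = 1, seed = 1L,
                             study_start = "2016-08-01",
                             weekly_events_per_participant = 6,
                             low_wear_frac = 0.1) {
  assert_scalar_number(n_participants, "n_participants", lower = 1)
  assert_scalar_number(n_external, "n_external", lower = 0)
  assert_scalar_number(n_weeks, "n_weeks", lower = 1)
  assert_scalar_number(coupling_rho, "coupling_rho", 0, 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(low_wear_frac, "low_wear_frac", 0, 1)
  structure(list(
    n_participants = as.integer(n_participants),
    n_external = as.integer(n_external),
    n_weeks = as.integer(n_weeks),
    coupling_rho = coupling_rho,
    label_beta_behavior = label_beta_behavior,
    label_beta_network = label_beta_network,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    study_start = as.Date(study_start),
    weekly_events_per_participant = weekly_events_per_participant,
    low_wear_frac = low_wear_frac,
    # heart-rate model: per-minute hr = baseline_i + state bump + noise
    hr_baseline_mean = 70, hr_baseline_sd = 5,
    hr_state_bump = c(sedentary = 0, lightly = 8, fairly = 20, very = 35),
    hr_noise_scale = 3,
    # lognormal propensities (heavy-tailed contact rates and step scales)
    sociability_sdlog = 0.8, fitness_meanlog = log(8000), fitness_sdlog = 0.35
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  cohort : %d participants + %d externals, %d weeks\n",
              x$n_participants, x$n_external, x$n_weeks))
  cat(sprintf("  coupling_rho %.2f | label betas (behavior %.2f, network %.2f) | noise_sd %.2f\n",
              x$coupling_rho, x$label_beta_behavior, x$label_beta_network, x$noise_sd))
  cat("  seed   :", x$seed, "\n")
  invisible(x)
}

# Shared smooth weekly factor: two sinusoids plus a linear drift with
# seed-dependent phases, standardized over the window. Communication rates
# and daily activity are both multiplied by exp(0.4 * coupling_rho * S_w).
weekly_factor <- function(config) {
  set.seed(derive_seed(config$seed, "weekly_factor"))
  w <- seq_len(config$n_weeks) - 1
  phi <- runif(2, 0, 2 * pi)
  drift <- runif(1, -0.5, 0.5)
  s <- sin(2 * pi * w / config$n_weeks + phi[1]) +
    0.5 * sin(4 * pi * w / config$n_weeks + phi[2]) +
    drift * (w - mean(w)) / max(config$n_weeks / 2, 1)
  if (sd(s) > 0) s <- (s - mean(s)) / sd(s)
  s
}

coupling_multiplier <- function(config, s_w) {
  exp(0.4 * config$coupling_rho * s_w)
}

#' Generate latent participant profiles and survey labels
#'
#' Draws per-participant sociability (mean contact rate) and fitness (daily
#' step scale) from lognormal distributions, assigns gender, and converts a
#' latent wellness score
#' `beta_b * z(log fitness) + beta_n * z(log sociability) + noise` into
#' ordinal survey labels by empirical-quantile thresholding at fixed
#' cumulative level proportions (4 levels for stress/happiness/health, 5 for
#' positive attitude).
#'
#' @param config a [generator_config()].
#' @return list with `profiles` (data.table: participant, sociability,
#'   fitness, gender, one `latent_*` column per attribute) and `survey`
#'   (data.table accepted by [read_survey()] round-trip).
#' @export
generate_cohort <- function(config) {
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  sociability <- rlnorm(n, meanlog = 0, sdlog = config$sociability_sdlog)
  fitness <- rlnorm(n, meanlog = config$fitness_meanlog, sdlog = config$fitness_sdlog)
  gender <- ifelse(runif(n) < 0.45, "male", "female")

  zb <- z_score(log(fitness))
  zn <- z_score(log(sociability))
  profiles <- data.table::data.table(
    participant = ids, sociability = sociability, fitness = fitness,
    gender = gender
  )
  survey <- data.table::data.table(participant = ids, gender = gender)
  for (attr_name in names(WELLNESS_RANGES)) {
    latent <- config$label_beta_behavior * zb + config$label_beta_network * zn +
      rnorm(n, 0, config$noise_sd)
    cuts <- quantile(latent, probs = LABEL_CUT_PROBS[[attr_name]], names = FALSE)
    label <- findInterval(latent, cuts) + 1L
    profiles[[paste0("latent_", attr_name)]] <- latent
    survey[[attr_name]] <- label
  }
  list(profiles = profiles, survey = survey)
}

#' Generate a communication event log
#'
#' Weekly event counts per pair are Poisson with rate proportional to the
#' product of the endpoints' sociabilities and the shared weekly coupling
#' multiplier. Pairs are all participant-participant and
#' participant-external combinations; many pairs end up with total counts
#' below the spurious-edge threshold so the edge filter is exercised.
#'
#' @param profiles `profiles` table from [generate_cohort()].
#' @param config a [generator_config()].
#' @return `data.table` of events in [read_comm_events()] layout (with week).
#' @export
generate_comm_log <- function(profiles, config) {
  set.seed(derive_seed(config$seed, "comm_log"))
  n_p <- nrow(profiles)
  n_x <- config$n_external
  soc_p <- profiles$sociability
  soc_x <- if (n_x > 0) {
    rlnorm(n_x, meanlog = 0, sdlog = config$sociability_sdlog)
  } else {
    numeric(0)
  }
  ids <- c(profiles$participant, if (n_x > 0) sprintf("X%03d", seq_len(n_x)))
  g <- c(soc_p, soc_x)
  g <- g / mean(g)
  n_all <- n_p + n_x

  # participant-participant and participant-external pairs only: every
  # logged event involves at least one enrolled phone.
  pp <- if (n_p >= 2) t(utils::combn(n_p, 2)) else matrix(integer(), 0, 2)
  px <- if (n_x > 0) {
    cbind(rep(seq_len(n_p), each = n_x), rep(n_p + seq_len(n_x), times = n_p))
  } else {
    matrix(integer(), 0, 2)
  }
  pairs <- rbind(pp, px)
  base_rate <- config$weekly_events_per_participant / max(n_all - 1, 1)
  pair_rate <- base_rate * g[pairs[, 1]] * g[pairs[, 2]]

  s_w <- weekly_factor(config)
  mult <- coupling_multiplier(config, s_w)
  n_pairs <- nrow(pairs)
  lambda <- rep(pair_rate, times = config$n_weeks) * rep(mult, each = n_pairs)
  counts <- rpois(length(lambda), lambda)
  keep <- counts > 0
  if (!any(keep)) return(empty_events())

  pair_idx <- rep(rep(seq_len(n_pairs), times = config$n_weeks)[keep], counts[keep])
  week_idx <- rep(rep(seq_len(config$n_weeks) - 1L, each = n_pairs)[keep], counts[keep])
  n_ev <- length(pair_idx)

  a <- ids[pairs[pair_idx, 1]]
  b <- ids[pairs[pair_idx, 2]]
  flip <- runif(n_ev) < 0.5
  src <- ifelse(flip, b, a)
  tgt <- ifelse(flip, a, b)
  channel <- ifelse(runif(n_ev) < 0.8, "text", "call")
  start <- as.POSIXct(config$study_start, tz = "UTC")
  ts <- start + week_idx * 7 * 86400 + runif(n_ev, 0, 7 * 86400 - 1)
  is_call <- channel == "call"
  duration <- ifelse(is_call, round(rexp(n_ev, rate = 1 / 180)), NA_real_)
  answered <- ifelse(is_call, runif(n_ev) < 0.85, NA)

  out <- data.table::data.table(
    timestamp = ts, source = src, target = tgt, channel = channel,
    duration_s = duration, answered = as.logical(answered),
    week = as.integer(week_idx)
  )
  data.table::setorder(out, timestamp)
  out[]
}

#' Generate a minute-level wearable stream
#'
#' Per participant-day the simulator draws worn minutes (a `low_wear_frac`
#' fraction of days fall short of the daily wear threshold), a daily step
#' target proportional to fitness times the weekly coupling multiplier, a
#' four-state activity mix whose fairly/very-active share rises with fitness
#' and the weekly factor, then emits one record per worn minute: heart rate
#' = participant baseline + state bump + noise, Poisson minute steps whose
#' expected daily sum is the step target. Non-wear minutes are simply
#' absent. Per day the four state-minute counts sum to worn minutes.
#'
#' @inheritParams generate_comm_log
#' @return `data.table` of minute records in [read_minute_records()] layout.
#' @export
generate_wearable_stream <- function(profiles, config) {
  set.seed(derive_seed(config$seed, "wearable"))
  n <- nrow(profiles)
  n_days <- config$n_weeks * 7L
  s_w <- weekly_factor(config)
  mult <- coupling_multiplier(config, s_w)

  day <- data.table::CJ(pi_ = seq_len(n), d = seq_len(n_days) - 1L)
  day[, week := d %/% 7L]
  nd <- nrow(day)

  low <- runif(nd) < config$low_wear_frac
  worn <- integer(nd)
  worn[low] <- as.integer(round(runif(sum(low), 300, 1100)))
  worn[!low] <- as.integer(pmin(1440, pmax(1150, round(rnorm(sum(!low), 1330, 50)))))
  day[, worn := worn]

  zf <- z_score(log(profiles$fitness))
  day[, target_steps := profiles$fitness[pi_] * mult[week + 1L] *
        exp(rnorm(nd, 0, 0.1))]
  # activity-state mix per day (shares of worn minutes)
  act <- 0.6 * zf[day$pi_] + 0.8 * config$coupling_rho * s_w[day$week + 1L]
  p_very <- plogis(-3.1 + act)
  p_fair <- plogis(-3.0 + act)
  p_light <- 0.22 * (1 - p_very - p_fair)
  p_sed <- 1 - p_very - p_fair - p_light

  # expand to minutes: worn minutes are a contiguous block with random onset
  offset <- as.integer(floor(runif(nd) * (1441 - day$worn)))
  minute_of_day <- sequence(day$worn, from = offset)
  di <- rep(seq_len(nd), day$worn)
  total <- length(di)

  u <- runif(total)
  c1 <- p_sed[di]; c2 <- c1 + p_light[di]; c3 <- c2 + p_fair[di]
  state_i <- 1L + (u > c1) + (u > c2) + (u > c3)
  state <- ACTIVITY_STATES[state_i]

  # per-minute step intensity by state; expected daily sum = target.
  # per-day weight totals via cumulative sums over the contiguous day blocks
  wt <- c(0.02, 1, 3, 5)[state_i]
  ends <- cumsum(day$worn)
  cs <- cumsum(wt)
  wt_day <- cs[ends] - c(0, cs[ends[-nd]])
  lambda <- day$target_steps[di] * wt / wt_day[di]
  steps <- rpois(total, lambda)

  hr_base <- rnorm(n, config$hr_baseline_mean, config$hr_baseline_sd)
  hr <- hr_base[day$pi_[di]] + config$hr_state_bump[state_i] +
    rnorm(total, 0, config$hr_noise_scale * config$noise_sd)
  hr <- pmax(hr, 30)

  start <- as.POSIXct(config$study_start, tz = "UTC")
  day_sec <- as.numeric(start) + day$d * 86400
  ts <- .POSIXct(day_sec[di] + minute_of_day * 60, tz = "UTC")

  # rows are already participant-major and time-ascending by construction;
  # setDT avoids copying the minute-level columns
  out <- data.table::setDT(list(
    participant = profiles$participant[day$pi_[di]],
    timestamp = ts, heart_rate = hr, steps = steps, state = state,
    week = as.integer(day$week[di])
  ))
  out[]
}

#' Simulate a full synthetic study
#'
#' Runs the three generators under one root seed and assembles the matching
#' [study_config()]. Optionally writes the three standard CSVs plus a
#' ground-truth JSON (profiles, weekly factor, configuration) for recovery
#' tests.
#'
#' @param config a [generator_config()].
#' @param dir optional output directory; created if missing.
#' @return list with `events`, `minutes`, `survey`, `profiles`,
#'   `weekly_factor`, `study` (a [study_config()]) and `config`.
#' @export
simulate_study <- function(config = generator_config(), dir = NULL) {
  cohort <- generate_cohort(config)
  events <- generate_comm_log(cohort$profiles, config)
  minutes <- generate_wearable_stream(cohort$profiles, config)
  study <- study_config(config$study_start, roster = cohort$profiles$participant,
                        n_weeks = config$n_weeks, seed = config$seed)
  out <- list(events = events, minutes = minutes, survey = cohort$survey,
              profiles = cohort$profiles, weekly_factor = weekly_factor(config),
              study = study, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_comm_events(events, file.path(dir, "comm_events.csv"))
    write_minute_records(minutes, file.path(dir, "minute_records.csv"))
    write_survey(cohort$survey, file.path(dir, "survey.csv"))
    truth <- list(
      weekly_factor = out$weekly_factor,
      profiles = as.data.frame(cohort$profiles),
      config = unclass(config)[c("n_participants", "n_external", "n_weeks",
                                 "coupling_rho", "label_beta_behavior",
                                 "label_beta_network", "noise_sd", "seed")]
    )
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
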