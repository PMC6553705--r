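# Structure-behavior coupling analysis: zero-lag normalized
# cross-correlation of weekly series, thresholded pair counting at cohort
# and individual level, multiplicity-corrected high/low tests, and one-way
# ANOVA of heart rate across wellness levels.

# The six weekly behavioral means paired against structure.
BEHAVIOR_MEANS <- c("hr_mean", "steps_mean", "sed_mean", "light_mean",
                    "fair_mean", "very_mean")
STRUCTURE_METRICS <- c("degree", "triangles", "clustering", "betweenness",
                       "closeness")

# The 60 structure-behavior pairs: 5 metrics x 2 network variants x 6
# behavioral means.
pair_grid <- function() {
  data.table::CJ(variant = c("participant", "whole"),
                 structure_feature = STRUCTURE_METRICS,
                 behavior_feature = BEHAVIOR_MEANS)
}

#' Zero-lag normalized cross-correlation
#'
#' `r = sum((x - mean(x)) * (y - mean(y))) / sqrt(sum((x - mean(x))^2) *
#' sum((y - mean(y))^2))` -- the Pearson coefficient of the two aligned
#' weekly series -- with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against `t(n - 2)`. Weeks where
#' either series is missing are dropped pairwise first. Series shorter than
#' 3 usable points or constant give `r = NA` with `defined = FALSE`.
#'
#' @param x,y numeric series of equal length.
#' @return list: `r`, `p`, `n` (points used), `defined`.
#' @export
ncc <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  undefined <- list(r = NA_real_, p = NA_real_, n = n, defined = FALSE)
  if (n < 3) return(undefined)
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) return(undefined)
  r <- sum(dx * dy) / sqrt(sx * sy)
  r <- max(min(r, 1), -1)
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n, defined = TRUE)
}

# Weekly cohort series: central tendency across participants per week for
# the 6 behavioral means and the 10 structural features.
cohort_weekly_series <- function(behavior, structure, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) median(x, na.rm = TRUE)
  }
  beh <- data.table::as.data.table(behavior)[
    , lapply(.SD, f), by = week, .SDcols = BEHAVIOR_MEANS]
  str <- data.table::as.data.table(structure)[
    , lapply(.SD, f), by = .(week, variant), .SDcols = STRUCTURE_METRICS]
  list(behavior = beh[order(week)], structure = str[order(variant, week)])
}

#' Cohort-level correlation matrix over the sixty pairs
#'
#' For every combination of a structural feature (5 metrics x 2 network
#' variants) and a behavioral mean (6), correlates the weekly
#' cross-participant central-tendency series via [ncc()].
#'
#' @param behavior weekly behavioral table ([behavior_feature_table()]).
#' @param structure weekly structural table ([structural_feature_table()]).
#' @param stat cohort central tendency, `"mean"` (default) or `"median"`.
#' @return `data.table` with one row per pair: variant, structure_feature,
#'   behavior_feature, r, p, n, defined.
#' @export
cohort_pair_matrix <- function(behavior, structure, stat = "mean") {
  series <- cohort_weekly_series(behavior, structure, stat)
  grid <- pair_grid()
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i]
    s <- series$structure[variant == g$variant]
    merged <- merge(series$behavior[, c("week", g$behavior_feature), with = FALSE],
                    s[, c("week", g$structure_feature), with = FALSE], by = "week")
    cc <- ncc(merged[[g$structure_feature]], merged[[g$behavior_feature]])
    res[[i]] <- data.table::data.table(
      variant = g$variant, structure_feature = g$structure_feature,
      behavior_feature = g$behavior_feature,
      r = cc$r, p = cc$p, n = cc$n, defined = cc$defined
    )
  }
  data.table::rbindlist(res)
}

#' Count pairs at or above an absolute-correlation threshold
#'
#' @param matrix pair table from [cohort_pair_matrix()].
#' @param tau threshold in `[0, Inf)`; comparison is `|r| >= tau`
#'   (inclusive). Undefined entries are never counted.
#' @return integer count.
#' @export
count_pairs <- function(matrix, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("`tau` must be a nonnegative number", call. = FALSE)
  }
  sum(matrix$defined & abs(matrix$r) >= tau, na.rm = TRUE)
}

#' Per-person correlation counts
#'
#' Correlates each participant's own weekly series for every
#' structure-behavior pair and counts, per pair, the participants with
#' `|r| >= tau`; and per behavioral feature, the participants whose series
#' reaches the threshold for at least one structural feature of the
#' participant network, the whole network, or either. Participants with
#' fewer than `min_weeks` usable weeks for a pair are excluded from that
#' pair; the per-feature denominators count participants usable for at
#' least one pair. Percentages are `round(100 * count / denominator)`.
#'
#' @param behavior weekly behavioral table.
#' @param structure weekly structural table.
#' @param tau absolute-correlation threshold (default 0.5).
#' @param min_weeks minimum usable weeks per participant (default 3).
#' @param signed if `TRUE` count `r >= tau` instead of `|r| >= tau`.
#' @return list with `per_pair` (variant, structure_feature,
#'   behavior_feature, count, denominator), `per_behavior`
#'   (behavior_feature, participant/whole/either counts and percentages,
#'   denominator), and `person_r` (the per-participant coefficients).
#' @export
per_person_counts <- function(behavior, structure, tau = 0.5, min_weeks = 3L,
                              signed = FALSE) {
  beh <- data.table::as.data.table(behavior)
  str <- data.table::as.data.table(structure)
  long_beh <- data.table::melt(beh[, c("participant", "week", BEHAVIOR_MEANS), with = FALSE],
                               id.vars = c("participant", "week"),
                               variable.name = "behavior_feature",
                               value.name = "b", variable.factor = FALSE)
  long_str <- data.table::melt(str[, c("participant", "week", "variant", STRUCTURE_METRICS), with = FALSE],
                               id.vars = c("participant", "week", "variant"),
                               variable.name = "structure_feature",
                               value.name = "s", variable.factor = FALSE)
  merged <- merge(long_str, long_beh, by = c("participant", "week"),
                  allow.cartesian = TRUE)
  person_r <- merged[, {
    cc <- ncc(s, b)
    .(r = cc$r, n = cc$n, defined = cc$defined && cc$n >= min_weeks)
  }, by = .(participant, variant, structure_feature, behavior_feature)]

  hit <- if (signed) {
    person_r$defined & !is.na(person_r$r) & person_r$r >= tau
  } else {
    person_r$defined & !is.na(person_r$r) & abs(person_r$r) >= tau
  }
  person_r[, hit := hit]

  per_pair <- person_r[, .(count = sum(hit), denominator = sum(defined)),
                       by = .(variant, structure_feature, behavior_feature)]

  by_person <- person_r[, .(
    hit_participant = any(hit[variant == "participant"]),
    hit_whole = any(hit[variant == "whole"]),
    hit_either = any(hit),
    usable = any(defined)
  ), by = .(participant, behavior_feature)]
  per_behavior <- by_person[, .(
    participant_count = sum(hit_participant & usable),
    whole_count = sum(hit_whole & usable),
    either_count = sum(hit_either & usable),
    denominator = sum(usable)
  ), by = behavior_feature]
  per_behavior[, `:=`(
    participant_pct = round_half_away(100 * participant_count / denominator),
    whole_pct = round_half_away(100 * whole_count / denominator),
    either_pct = round_half_away(100 * either_count / denominator)
  )]
  list(per_pair = per_pair[], per_behavior = per_behavior[], person_r = person_r[])
}

#' High/low tests across the sixty pairs
#'
#' For each structure-behavior pair, splits the weeks at the median of the
#' cohort structure series (strictly above the median = high, otherwise
#' low), runs a Welch two-sample t-test on the cohort behavior series
#' values of the two groups, and adjusts the sixty p-values with
#' Benjamini-Hochberg (default) at level `alpha`. Pairs with fewer than 2
#' weeks on either side are skipped and flagged.
#'
#' @inheritParams cohort_pair_matrix
#' @param alpha significance level after adjustment (default 0.05).
#' @param method multiplicity correction passed to [stats::p.adjust()]
#'   (default `"BH"`; `"bonferroni"` available).
#' @return `data.table`: variant, structure_feature, behavior_feature, t,
#'   p_raw, p_adjusted, significant, skipped.
#' @export
high_low_tests <- function(behavior, structure, stat = "mean", alpha = 0.05,
                           method = "BH") {
  series <- cohort_weekly_series(behavior, structure, stat)
  grid <- pair_grid()
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i]
    s <- series$structure[variant == g$variant]
    merged <- merge(series$behavior[, c("week", g$behavior_feature), with = FALSE],
                    s[, c("week", g$structure_feature), with = FALSE], by = "week")
    sv <- merged[[g$structure_feature]]
    bv <- merged[[g$behavior_feature]]
    ok <- is.finite(sv) & is.finite(bv)
    sv <- sv[ok]; bv <- bv[ok]
    high <- sv > median(sv)
    row <- data.table::data.table(
      variant = g$variant, structure_feature = g$structure_feature,
      behavior_feature = g$behavior_feature,
      t = NA_real_, p_raw = NA_real_, skipped = TRUE
    )
    if (sum(high) >= 2 && sum(!high) >= 2 &&
        (sd(bv[high]) > 0 || sd(bv[!high]) > 0)) {
      tst <- t.test(bv[high], bv[!high])
      row[, `:=`(t = unname(tst$statistic), p_raw = tst$p.value, skipped = FALSE)]
    }
    res[[i]] <- row
  }
  out <- data.table::rbindlist(res)
  out[, p_adjusted := NA_real_]
  out[skipped == FALSE, p_adjusted := p.adjust(p_raw, method = method)]
  out[, significant := !is.na(p_adjusted) & p_adjusted <= alpha]
  out[]
}

#' One-way ANOVA of mean heart rate across wellness levels
#'
#' For each wellness attribute, tests whether participants' overall mean
#' heart rates differ across the ordinal levels of that attribute.
#'
#' @param behavior weekly behavioral table.
#' @param survey survey table from [read_survey()] or [generate_cohort()].
#' @return `data.table`: attribute, F, p, n, n_levels.
#' @export
anova_by_level <- function(behavior, survey) {
  beh <- data.table::as.data.table(behavior)
  person_hr <- beh[!is.na(hr_mean), .(hr = mean(hr_mean)), by = participant]
  sv <- data.table::as.data.table(survey)
  out <- list()
  for (attr_name in names(WELLNESS_RANGES)) {
    d <- merge(person_hr, sv[, c("participant", attr_name), with = FALSE],
               by = "participant")
    data.table::setnames(d, attr_name, "level")
    d <- d[!is.na(level)]
    tab <- table(d$level)
    tab <- tab[tab >= 2]
    d <- d[level %in% as.integer(names(tab))]
    if (length(tab) < 2) {
      stop(sprintf("anova_by_level: fewer than 2 populated levels for %s", attr_name),
           call. = FALSE)
    }
    fit <- aov(hr ~ factor(level), data = d)
    s <- summary(fit)[[1]]
    out[[attr_name]] <- data.table::data.table(
      attribute = attr_name, F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
      n = nrow(d), n_levels = length(tab)
    )
  }
  data.table::rbindlist(out)
}
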