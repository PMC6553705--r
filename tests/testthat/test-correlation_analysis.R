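test_that("ncc reproduces hand-computed Pearson values", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(ncc(x, x)$r, 1)
  expect_equal(ncc(x, -x)$r, -1)
  expect_equal(ncc(c(1, 2, 3), c(1, 2, 4))$r, 0.982, tolerance = 1e-3)
  # r = 0.84 over 22 weekly points is significant at the 5% level
  set.seed(2)
  repeat {
    a <- rnorm(22); b <- 0.84 * scale(a)[, 1] + sqrt(1 - 0.84^2) * rnorm(22)
    got <- ncc(a, b)
    if (abs(got$r - 0.84) < 0.05) break
  }
  expect_lt(got$p, 0.05)
})

test_that("ncc handles degenerate series and matches cor.test", {
  expect_false(ncc(c(1, 1, 1), c(1, 2, 3))$defined)
  expect_false(ncc(c(1, 2), c(3, 4))$defined)
  # pairwise deletion of missing weeks
  x <- c(1, 2, NA, 4, 5); y <- c(2, 4, 9, 8, 10)
  got <- ncc(x, y)
  expect_equal(got$n, 4)
  ref <- cor.test(x[-3], y[-3])
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("ncc is symmetric and scale-invariant over random series", {
  set.seed(77)
  for (trial in 1:200) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    a <- runif(1, -3, 3); b <- runif(1, -5, 5)
    if (a == 0) a <- 1
    r1 <- ncc(x, y)$r
    expect_equal(ncc(y, x)$r, r1, tolerance = 1e-12)
    expect_equal(ncc(a * x + b, y)$r, sign(a) * r1, tolerance = 1e-9)
    # brute-force formula evaluation
    bf <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r1, bf, tolerance = 1e-12)
  }
})

test_that("the cohort matrix has exactly sixty pairs and detects identity", {
  run <- cached_default_run()
  pm <- cohort_pair_matrix(run$behavior, run$structure)
  expect_equal(nrow(pm), 60)
  expect_equal(nrow(unique(pm[, .(variant, structure_feature, behavior_feature)])), 60)
  # duplicating a behavior series as a fake structure feature gives r = 1
  st_fake <- data.table::copy(run$structure)
  beh_means <- run$behavior[, .(m = mean(hr_mean, na.rm = TRUE)), by = .(participant, week)]
  st_fake <- merge(st_fake, beh_means, by = c("participant", "week"))
  st_fake[, degree := m][, m := NULL]
  pm_fake <- cohort_pair_matrix(run$behavior, st_fake)
  expect_equal(pm_fake[variant == "whole" & structure_feature == "degree" &
                         behavior_feature == "hr_mean", r], 1, tolerance = 1e-9)
})

test_that("count_pairs applies an inclusive threshold and is monotone in tau", {
  m <- data.table::data.table(r = c(0.7, 0.5, 0.49, -0.6), defined = TRUE)
  expect_equal(count_pairs(m, 0.5), 3)
  expect_equal(count_pairs(m, 1.1), 0)
  expect_error(count_pairs(m, -0.1), "nonnegative")
  m2 <- data.table::data.table(r = rep(c(1, -1), 30), defined = TRUE)
  expect_equal(count_pairs(m2, 0.5), 60)
  run <- cached_default_run()
  pm <- cohort_pair_matrix(run$behavior, run$structure)
  taus <- seq(0, 1, by = 0.1)
  counts <- vapply(taus, function(t) count_pairs(pm, t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("median and mean cohort statistics both produce full matrices", {
  run <- cached_default_run()
  pm_med <- cohort_pair_matrix(run$behavior, run$structure, stat = "median")
  expect_equal(nrow(pm_med), 60)
  expect_true(all(abs(pm_med$r[pm_med$defined]) <= 1))
})

test_that("per-person counts satisfy the union inequality and catch identical series", {
  run <- cached_default_run()
  pc <- per_person_counts(run$behavior, run$structure)
  expect_true(all(pc$per_behavior$either_count >=
                    pmax(pc$per_behavior$participant_count, pc$per_behavior$whole_count)))
  expect_true(all(pc$per_behavior$denominator <= run$sim$config$n_participants))
  expect_equal(nrow(pc$per_pair), 60)
  # a participant whose degree series is duplicated into steps is always counted
  st <- run$structure
  one <- st[variant == "whole" & participant == st$participant[1]]
  beh_dup <- data.table::copy(run$behavior)
  beh_dup[participant == one$participant[1],
          steps_mean := one$degree[match(week, one$week)] + 0.001 * week]
  pc2 <- per_person_counts(beh_dup, run$structure)
  hit <- pc2$person_r[participant == one$participant[1] & variant == "whole" &
                        structure_feature == "degree" & behavior_feature == "steps_mean"]
  expect_true(hit$hit)
})

test_that("participants with too few usable weeks are excluded from counts", {
  run <- cached_default_run()
  beh <- data.table::copy(run$behavior)
  victim <- beh$participant[1]
  beh[participant == victim & week > 1, (netwell:::BEHAVIOR_FEATURES) := NA_real_]
  pc <- per_person_counts(beh, run$structure, min_weeks = 3)
  expect_true(all(pc$person_r[participant == victim & behavior_feature == "hr_mean",
                              !defined]))
  full_n <- length(unique(beh$participant))
  expect_true(all(pc$per_behavior[behavior_feature == "hr_mean", denominator] < full_n))
})

test_that("high/low tests behave at the null, under shift, and under BH identities", {
  # identical behavior in both groups -> p close to 1 impossible to reject
  set.seed(12)
  weeks <- 0:21
  st <- data.table::CJ(participant = "A", week = weeks, variant = c("whole", "participant"))
  st[, (netwell:::STRUCTURE_METRICS) := lapply(1:5, function(i) rnorm(.N))]
  beh <- data.table::data.table(participant = "A", week = weeks)
  beh[, (netwell:::BEHAVIOR_MEANS) := lapply(1:6, function(i) rep(5, .N))]
  hl <- high_low_tests(beh, st)
  expect_true(all(hl$skipped))   # constant behavior: no variance to test

  beh2 <- data.table::copy(beh)
  beh2[, (netwell:::BEHAVIOR_MEANS) := lapply(1:6, function(i) rnorm(.N, 0, 1))]
  # plant a +10 sd shift in hr_mean for the weeks where whole-network degree is high
  hi <- st[variant == "whole", week[degree > median(degree)]]
  beh2[week %in% hi, hr_mean := hr_mean + 10]
  hl2 <- high_low_tests(beh2, st)
  planted <- hl2[variant == "whole" & structure_feature == "degree" &
                   behavior_feature == "hr_mean"]
  expect_true(planted$significant)
  # BH identity: p.adjust of equal p-values keeps them equal
  expect_equal(p.adjust(rep(0.001, 60), method = "BH"), rep(0.001, 60))
  expect_true(all(hl2$p_adjusted >= hl2$p_raw - 1e-12, na.rm = TRUE))
})

test_that("heart-rate ANOVA recovers level differences and the F = t^2 identity", {
  # identical group means -> F near 0 scale
  set.seed(9)
  beh <- data.table::data.table(participant = sprintf("P%02d", 1:40), week = 0L,
                                hr_mean = rnorm(40, 70, 5))
  sv <- data.table::data.table(participant = beh$participant, gender = "female",
                               stress = rep(1:4, each = 10),
                               happiness = rep(1:2, 20),
                               positive_attitude = rep(1:5, 8),
                               health = rep(1:4, 10))
  res <- anova_by_level(beh, sv)
  expect_equal(nrow(res), 4)
  expect_true(all(res$p > 0.001))

  # two equal-size groups: F equals the square of the pooled t statistic
  two <- data.table::copy(sv)[, stress := rep(1:2, each = 20)]
  res2 <- anova_by_level(beh, two)
  g1 <- beh$hr_mean[1:20]; g2 <- beh$hr_mean[21:40]
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(res2[attribute == "stress", F], unname(tt$statistic)^2, tolerance = 1e-9)

  # labels driven by heart rate are detected
  beh3 <- data.table::data.table(participant = sprintf("Q%03d", 1:300), week = 0L,
                                 hr_mean = rnorm(300, 70, 5))
  lab <- cut(beh3$hr_mean + rnorm(300, 0, 1), breaks = quantile(beh3$hr_mean, c(0, .25, .5, .75, 1)),
             labels = FALSE, include.lowest = TRUE)
  sv3 <- data.table::data.table(participant = beh3$participant, gender = "male",
                                stress = lab, happiness = lab,
                                positive_attitude = lab, health = lab)
  res3 <- anova_by_level(beh3, sv3)
  expect_true(all(res3$p < 0.001))

  # a single populated level errors
  sv_bad <- data.table::copy(sv)[, stress := 2L]
  expect_error(anova_by_level(beh, sv_bad), "fewer than 2")
})
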