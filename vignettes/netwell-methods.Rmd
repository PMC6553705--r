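---
title: "Methods: network structure, wearable behavior, and wellness prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network structure, wearable behavior, and wellness prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

netwell studies a cohort of participants who carry a wearable device
(minute-level heart rate, steps, and a four-state activity classification)
and a phone app that logs their calls and texts. Two questions drive the
design:

1. **Structure vs. behavior.** Do weekly summaries of a person's position
   in the communication network (degree, triangles, clustering,
   betweenness, closeness) co-vary over the semester with weekly summaries
   of their physical behavior (heart rate, steps, activity-state minutes)?
2. **Prediction.** Do those structural features improve prediction of
   ordinal wellness states (stress, happiness, positive attitude,
   self-assessed health, reported once on a 4- or 5-point Likert scale)
   over gender + behavioral features alone?

## Data model and preprocessing

Weeks are consecutive 7-day bins anchored at the configured study start
(`assign_week`), not calendar ISO weeks: the binning is then reproducible
without locale assumptions. The default window is 22 weeks.

Two preprocessing rules gate everything downstream:

* **Daily wear rule.** A minute counts as worn iff its heart rate is
  non-missing (optical heart rate is the usual wear proxy). A
  participant-day enters the weekly features only with at least 1140 worn
  minutes (19 of 24 hours). The unit eliminated is the participant-day,
  not the week: a week keeps whatever valid days remain, and
  `n_valid_days` is carried alongside the features.
* **Spurious-edge rule.** An undirected pair is dropped entirely unless it
  accumulates at least 3 events (calls + texts, both directions) over the
  whole window; this removes spam-like contacts. The threshold is applied
  once, globally — a retained pair then contributes an edge to week *w*
  iff it has at least one event that week. We read the published rule as a
  window-level filter; re-applying it per week would empty most weekly
  graphs.

Duplicate participant-minutes are resolved keep-first with a warning
(deterministic, order-stable); ordinal survey answers are validated
against their Likert ranges at ingest.

## Weekly networks and structural features

Networks are undirected and unweighted. Two variants are built per week:
the **whole network** (roster plus every external contact active on a
retained edge) and the **participant network** (roster only). Calls and
texts are pooled; durations and answered flags are retained in the data
model but never enter the structure.

Per node and week we compute degree, triangle count, local clustering
`2T/(d(d-1))` (0 when `d < 2`), betweenness normalized by `(n-1)(n-2)/2`,
and Wasserman–Faust component-scaled closeness
`((r-1)/(n-1)) * ((r-1)/sum d)` with `r` the reachable-set size including
the node. Weekly communication graphs are typically disconnected, and the
scaled variants keep both centralities in `[0, 1]` there; isolated nodes
get closeness 0. Roster members without edges stay in the graph as
degree-0 nodes with all-zero features, so the participant × week feature
table is rectangular — the prediction stage needs complete vectors, and a
week without communication is a real observation, not a missing one.

The implementation rides on igraph except for the closeness scaling,
which is computed from the distance matrix directly. All five features
are checked against an igraph-free brute-force oracle (Floyd–Warshall
distances, explicit path and triple enumeration) on random graphs of up
to 8 nodes.

## Weekly behavioral features

Twelve features per participant-week: pooled heart-rate mean and
**population variance** over all worn minutes of valid days; mean and
**sample (n−1) sd** over valid days of daily steps and of daily minutes in
each activity state. The mix of variance (heart rate) and sd (steps,
states) follows the emulated protocol exactly. The minute pool is close
to a census of the week (~8000 minutes), hence the population variance;
daily totals are a small sample of at most 7 days, hence the sample sd.
With a single valid day the sd is 0 by convention — documented, never
negative or undefined downstream. A week with zero valid days is emitted
with missing features and `n_valid_days = 0`; participants need
`min_weeks` (default 3) usable weeks to enter per-person correlations.

## Correlation analysis

"Normalized cross-correlation" is the zero-lag Pearson coefficient of two
aligned weekly series (the analysis produces one coefficient per pair,
not a lag function), with a two-sided p-value from
`t = r sqrt((n-2)/(1-r^2))`. Three views:

* **Cohort level**: the 22-point series of cross-participant weekly means
  (medians available — both central tendencies are reported in the
  emulated analysis) for each of the 60 pairs (5 metrics × 2 network
  variants × 6 behavioral means), with counts of pairs at `|r| >= tau`,
  `tau` in {0.5, 0.7}. The threshold is inclusive (`no less than`), and
  absolute values are used so that strong negative couplings (whole-network
  betweenness typically anti-correlates with activity) count as couplings;
  a signed mode is exposed.
* **Person level**: the same 60 correlations on each participant's own
  weekly series, counting participants at `|r| >= 0.5` per pair and per
  behavioral feature (at least one structural feature of the participant
  network, the whole network, or either — the either-network count is a
  union and can never fall below the single-network counts). Percentages
  are `round(100 * count / denominator)`.
* **High/low tests**: for each pair, weeks are split at the median of the
  structure series (strictly above = high), a Welch t-test compares the
  behavior series between groups, and Benjamini–Hochberg at 0.05 adjusts
  across the 60 tests (the emulated protocol cites a multiple-test
  correction without naming one; BH is the default and Bonferroni a
  config option). The median split is the parameter-free reading of
  "high and low-value ranges"; with 22 distinct values it is an 11/11
  split. Pairs with a degenerate split or no variance are skipped and
  flagged rather than tested.

A one-way ANOVA (`stats::aov`) of participant mean heart rate across the
levels of each wellness attribute accompanies the correlation analysis.

## Wellness prediction

One instance per participant-week; the participant's single semester
label is attached to all of their weeks. Three feature sets: `baseline`
(gender + 12 behavioral), `network_only` (10 structural), `full` (all
23). Features are z-scored with training-split statistics only.

The default split unit is the **participant** (75/25, stratified by
label, largest-remainder allocation): all weeks of a person stay on one
side, since rows of one participant are near-duplicates and a row-level
split would leak identity into the test set. A row-level mode is provided
for fidelity with protocols that split data points directly.

Five base classifiers are tuned by stratified 5-fold grid-search CV on
the training split: KNN (neighbor counts; `caret::knn3` for full class
probabilities), CART (`rpart`, leaf sizes), SVM (`e1071`, linear /
polynomial degree 2–3 / RBF kernels with a small cost grid, Platt
probabilities), multinomial logistic regression (`nnet::multinom`,
regularization decay), and random forest (`randomForest`; the candidate
grid is 10–100 trees in steps of 5, and the default protocol fixes 35
trees for reported results). The three classifiers with highest mean CV
accuracy form the ensemble (ties broken in the fixed order knn, cart,
svm, lr, rf).

The ensemble is weighted voting:
`y_vote = argmax_j sum_i w_ij p_ij`, with `p_ij` classifier `i`'s
predicted probability of class `j` and weights on a 0.1-step simplex
grid. The printed form of this rule equates `p_ij` with `w_ij`; we read
that as a typesetting slip — the objective is degenerate otherwise — and
treat the weights as free parameters. Two weight modes exist:

* `scalar` (default): one weight per classifier, constant across classes
  — 66 grid points for 3 classifiers, searched exhaustively.
* `per_class`: one simplex row per classifier as the printed constraint
  `sum_j w_ij = 1` states — 286 rows per classifier at K = 4, a cross
  product of ~2.3e7, searched by coordinate ascent (one classifier's row
  at a time until no improvement) rather than enumeration.

Weights are selected by the mean across folds of the macro-F1 of the
vote on held-out training folds, first-best in enumeration order on
ties; ties inside a vote resolve to the lowest class index. Since the
one-hot matrices are grid points, the selected weights can never be
CV-worse than the best single base classifier.

Reporting: per-class F1 with the zero rule, overall F1 as the unweighted
(macro) mean over all K classes ("averaged F1-Measures for all levels"),
a support-weighted variant alongside, a uniform-random baseline whose
per-class F1 has the closed form `2p/(Kp+1)` for class prevalence `p`,
and improvement percentages `round(100 (F1_full - F1_base)/F1_base)`
rounded half away from zero.

## The synthetic cohort

The simulator exists so that every stage is testable end to end without
the original (non-public) study data, and so that planted effects can be
recovered. It emulates: ~60 participants by default (325 mimics the
study's scale) plus 120 external contacts over 22 weeks; heavy-tailed
communication propensities and daily step scales (lognormal sociability
and fitness); a shared smooth weekly factor `S_w` (two sinusoids plus
drift, standardized) that multiplies both pairwise communication rates
and daily activity by `exp(0.4 rho S_w)` — `coupling_rho` in [0, 1] is
the planted structure–behavior coupling, and a smooth common factor is
the minimal structure that produces semester-long co-trending weekly
series; Poisson pair-week event counts proportional to
`sociability_i * sociability_j`, so many pairs fall under the 3-event
filter; minute-level wearables with a contiguous worn block per day
(about 10% of days are generated short of the wear threshold to exercise
the wear rule), a four-state activity mix whose active share rises with
fitness and `S_w`, Poisson minute steps summing to a fitness- and
week-scaled daily target, and heart rate = personal baseline + state bump
+ noise; ordinal labels by thresholding the latent score
`beta_b z(log fitness) + beta_n z(log sociability) + noise` at fixed
cumulative level proportions that mimic skewed Likert marginals (rare
extreme-low levels), 4 levels for stress/happiness/health and 5 for
positive attitude.

Default effect sizes (`coupling_rho = 0.9`, `label_beta_behavior = 0.8`,
`label_beta_network = 1.2`, `noise_sd = 1`) were fixed once, at design
time, by Monte-Carlo checks of the planted-effect recovery properties
(cohort degree–steps correlation >= 0.6 under coupling; <= 5 of 60 pairs
above 0.5 under the null; label–propensity association present and
absent as the betas dictate; a reliable full-over-baseline prediction
margin when the network effect is planted). The network effect size is
deliberately the larger of the two so that the structural features carry
label information the behavioral features cannot substitute for. What the simulator does **not** emulate:
community structure in the network (triangle counts are low), circadian
rhythm within days, device-specific step/heart-rate artifacts, survey
non-response patterns, or any attempt to fit the real cohort's
distributions. Passing recovery tests therefore show that the pipeline
detects the kind of coupling it was designed for — not that real data
contain it.

## Numerical choices and problem sizes

* All randomness flows from one root seed through named sub-streams
  (`derive_seed`), so every generator and the full pipeline are
  deterministic per seed.
* Correlations need at least 3 usable points and non-constant series;
  undefined coefficients are flagged and never counted.
* The repeated-seed simulation studies (correlation recovery over 10
  seeds, false-discovery control over 50 seeds at 30 participants,
  feature-set comparison over 2 × 10 seeds) use the reduced classifier
  grids (`classifier_grids(fast = TRUE)`) and the stress attribute; these
  sizes keep a full study on one CPU in minutes while leaving the Monte
  Carlo margins comfortable.
* Percentages round half away from zero (base R's `round` is
  half-to-even, which disagrees with reported percentages at exact
  halves).

## Known limitations

* The high/low t-test design (median split over weeks of the cohort
  series) is one admissible reading of an under-specified protocol;
  alternatives (per-person splits, tertile contrasts) are not provided.
* Likert labels are treated as unordered classes; no ordinal-regression
  treatment.
* Per-person correlation counting uses `|r|`; whether the original
  counting was signed is ambiguous (a signed mode is exposed).
* The whole-network closeness/betweenness depend on which externals are
  active in a week; externals with no retained edges vanish from the
  graph, which is a modeling choice, not an observation about reality.
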