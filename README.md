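# netwell

Does the *structure* of a person's communication network — not the content,
just who they call and text — track and predict their health behavior and
wellness? netwell is an R package for analysts of digital-phenotyping
cohorts (wearable + phone-log + survey studies) that implements the full
pipeline for that question:

1. **Ingest** communication event logs, minute-level wearable records, and
   ordinal wellness surveys (CSV).
2. **Build** weekly undirected, unweighted communication networks — a
   *whole network* including external contacts and a *participant network*
   restricted to the enrolled roster — after removing spurious edges
   (pairs with fewer than 3 events over the window), and extract five
   structural features per person per week: degree, triangles, local
   clustering, normalized betweenness, and Wasserman–Faust component-scaled
   closeness.
3. **Summarize** wearable streams into twelve weekly behavioral features
   (heart-rate mean/variance; mean/sd of daily steps and of daily minutes
   in four activity states), after discarding participant-days with less
   than 1140 worn minutes (19 of 24 hours).
4. **Correlate** structure and behavior: for each of the 60 pairs (5
   metrics x 2 networks x 6 behavioral means), the zero-lag normalized
   cross-correlation

   `r = sum((x_i - x̄)(y_i - ȳ)) / sqrt(sum((x_i - x̄)²) sum((y_i - ȳ)²))`

   of the weekly cohort-mean series, per-person correlation counts at
   |r| ≥ 0.5, and median-split high/low Welch t-tests with
   Benjamini–Hochberg correction across the 60 tests.
5. **Predict** each ordinal wellness state (stress, happiness, positive
   attitude, self-assessed health) from participant-week feature vectors
   with a weighted-voting ensemble over the three best of five tuned base
   classifiers (KNN, CART, SVM, LR, RF):

   `y_vote = argmax_j Σ_i w_ij p_ij ,  Σ w = 1 on a 0.1-step simplex grid`

   comparing `baseline` (gender + behavior), `network_only`, and `full`
   feature sets against a uniform-random baseline, with macro and
   per-level F1 and relative-improvement percentages.

A synthetic-cohort simulator (`simulate_study`) generates event logs,
wearable streams and survey labels with a planted structure–behavior
coupling and controllable label effect sizes, so the whole pipeline is
testable end to end and planted effects are recoverable.

## Worked example

```r
library(netwell)

res <- run_pipeline(sim_config = generator_config(seed = 1),
                    attributes = "stress")

# cohort-level coupling between weekly mean degree and weekly mean steps
res$pair_matrix[variant == "whole" & structure_feature == "degree" &
                behavior_feature == "steps_mean"]
#>    variant structure_feature behavior_feature         r            p     n defined
#> 1:   whole            degree       steps_mean 0.9633414 6.798568e-13    22    TRUE

res$pair_counts
#> tau_0.5 tau_0.7
#>      48      36

res$predictions$stress$table
#>          model    overall    level1     level2    level3     level4
#> 1:      random  0.2317382 0.1063853  0.2549420 0.3053516  0.2602738
#> 2:    baseline  0.2697065 0.0000000  0.1690141 0.4668588  0.4429530
#> 3:     network  0.3854261 0.0000000  0.6329114 0.5140562  0.3947368
#> 4:        full  0.3091537 0.0000000  0.2836879 0.4648318  0.4880952
#> 5: improvement 15.0000000        NA 68.0000000 0.0000000 10.0000000
```

With the default simulator settings (60 participants, 22 weeks, coupling
0.9, seed 1) the degree–steps correlation of the weekly cohort means is
0.96 in the whole network, 48 of the 60 structure–behavior pairs reach
|r| ≥ 0.5, 48 of the 60 high/low tests stay significant after
Benjamini–Hochberg correction, and the full feature set improves macro-F1
over gender + behavior by 15% — the planted effects the simulator was
designed to exhibit (over 10 seeds the full set wins 8–10 times; single
seeds vary). The improvement row recomputes
`round(100·(full − baseline)/baseline)` per column, NA where the baseline
level F1 is 0; level 1 (about 4.5% prevalence, roughly three participants
at this cohort size) is often missed entirely by the non-random models.

With `coupling_rho = 0` and zero label effects the same pipeline finds
almost no pairs above threshold and no significant high/low tests after
correction — the analysis separates the coupled and uncoupled regimes.

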