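test_that("feature sets select the documented column counts", {
  run <- cached_default_run()
  ds_net <- assemble_dataset(run$features, "stress", "network_only")
  ds_base <- assemble_dataset(run$features, "stress", "baseline")
  ds_full <- assemble_dataset(run$features, "stress", "full")
  expect_equal(ncol(ds_net$x), 10)
  expect_equal(ncol(ds_base$x), 13)
  expect_equal(ncol(ds_full$x), 23)
  expect_false(any(is.na(ds_full$x)))
  expect_true(all(ds_full$y %in% 1:4))
})

test_that("rows with missing labels are excluded from modelling", {
  run <- cached_default_run()
  feats <- data.table::copy(run$features)
  victim <- feats$participant[1]
  feats[participant == victim, stress := NA_integer_]
  ds <- assemble_dataset(feats, "stress", "full")
  expect_false(victim %in% ds$participant)
  expect_gt(ds$n_dropped, 0)
})

test_that("participant-unit splits never leak a participant across sides", {
  run <- cached_default_run()
  ds <- assemble_dataset(run$features, "stress", "full")
  sp <- split_train_test(ds, frac = 0.75, unit = "participant", seed = 3)
  expect_length(intersect(unique(sp$train$participant), unique(sp$test$participant)), 0)
  expect_error(split_train_test(ds, frac = 1.0), "frac")
  # row mode: floor rule on the training count
  ds100 <- ds
  keep <- 1:100
  ds100$x <- ds$x[keep, ]; ds100$y <- ds$y[keep]
  ds100$participant <- ds$participant[keep]; ds100$week <- ds$week[keep]
  sp100 <- suppressWarnings(split_train_test(ds100, frac = 0.75, unit = "row", seed = 1))
  expect_length(sp100$train$y, 75)
  expect_length(sp100$test$y, 25)
})

test_that("splits are deterministic per seed and near-stratified", {
  run <- cached_default_run()
  ds <- assemble_dataset(run$features, "happiness", "full")
  a <- split_train_test(ds, seed = 9)
  b <- split_train_test(ds, seed = 9)
  expect_identical(a$train$participant, b$train$participant)
  c_ <- split_train_test(ds, seed = 10)
  expect_false(identical(a$train$participant, c_$train$participant))
  tr_prop <- prop.table(table(factor(a$train$y, levels = 1:4)))
  all_prop <- prop.table(table(factor(ds$y, levels = 1:4)))
  expect_true(all(abs(tr_prop - all_prop) < 0.12))
})

test_that("the default RF protocol uses 35 trees while the search grid has 19", {
  expect_equal(classifier_grids()$rf, seq(10, 100, by = 5))
  expect_length(classifier_grids()$rf, 19)
  set.seed(1)
  x <- matrix(rnorm(200 * 4), 200); colnames(x) <- paste0("f", 1:4)
  y <- sample(1:3, 200, TRUE)
  ds <- list(x = x, y = y, participant = paste0("p", 1:200), week = rep(0L, 200),
             n_classes = 3L)
  tuned <- tune_base_classifiers(ds, grids = classifier_grids(fast = TRUE),
                                 seed = 1, classifiers = "rf")
  expect_equal(tuned$fits$rf$params$ntree, 35L)
  # reproducible CV scores under a fixed seed
  tuned2 <- tune_base_classifiers(ds, grids = classifier_grids(fast = TRUE),
                                  seed = 1, classifiers = "rf")
  expect_equal(tuned$cv_accuracy, tuned2$cv_accuracy)
})

test_that("select_top3 sorts by CV accuracy with a fixed tie order", {
  scores <- c(svm = 0.60, knn = 0.55, rf = 0.58, lr = 0.50, cart = 0.45)
  expect_setequal(select_top3(scores), c("svm", "rf", "knn"))
  expect_equal(select_top3(scores), c("svm", "rf", "knn"))
  ties <- c(knn = 0.5, cart = 0.5, svm = 0.5, lr = 0.5, rf = 0.5)
  expect_equal(select_top3(ties), c("knn", "cart", "svm"))
  expect_error(select_top3(c(a = 1, b = 2)), "at least 3")
})

test_that("weight grids have the stars-and-bars sizes", {
  g <- enumerate_weight_grid("scalar", step = 0.1, n_classifiers = 3, n_classes = 4)
  expect_length(g$matrices, 66)
  expect_true(all(vapply(g$matrices, function(w) abs(sum(w[, 1]) - 1) < 1e-9, logical(1))))
  gp <- enumerate_weight_grid("per_class", step = 0.1, n_classes = 4)
  expect_equal(nrow(gp$rows), 286)
  expect_true(all(abs(rowSums(gp$rows) - 1) < 1e-9))
  g1 <- enumerate_weight_grid("scalar", step = 1)
  expect_length(g1$matrices, 3)   # the three one-hot matrices
  expect_error(enumerate_weight_grid("scalar", step = 0), "0, 1")
})

test_that("ensemble voting reduces to argmax under one-hot weights and breaks ties low", {
  p <- list(
    matrix(c(.5, .2, .2, .1), 1), matrix(c(.1, .6, .2, .1), 1),
    matrix(c(.3, .3, .3, .1), 1)
  )
  w_uniform <- matrix(1 / 3, 3, 4)
  expect_equal(ensemble_vote(p, w_uniform), 2)   # column sums .9 1.1 .7 .3
  w_hot2 <- matrix(0, 3, 4); w_hot2[2, ] <- 1
  expect_equal(ensemble_vote(p, w_hot2), 2)
  # one-hot reduction on random matrices
  set.seed(21)
  probs <- lapply(1:3, function(i) {
    m <- matrix(runif(40), 10, 4); m / rowSums(m)
  })
  for (i in 1:3) {
    w <- matrix(0, 3, 4); w[i, ] <- 1
    expect_equal(ensemble_vote(probs, w), max.col(probs[[i]], ties.method = "first"))
  }
  # exact two-column tie resolves to the lower class index
  tie <- matrix(c(.4, .4, .1, .1), 1)
  expect_equal(ensemble_vote(list(tie, tie, tie), w_uniform), 1)
  expect_error(ensemble_vote(list(probs[[1]], probs[[2]]), w_uniform), "dimension")
})

test_that("f1_report matches hand confusion-matrix values and the brute-force oracle", {
  rep1 <- f1_report(c(1, 1, 2, 2), c(1, 2, 2, 2), K = 2)
  expect_equal(rep1$per_class$f1, c(2 / 3, 0.8), tolerance = 1e-9)
  expect_equal(rep1$macro_f1, mean(c(2 / 3, 0.8)), tolerance = 1e-9)
  perfect <- f1_report(1:4, 1:4, 4)
  expect_true(all(perfect$per_class$f1 == 1))
  # class absent from both is zero and flagged
  rep0 <- f1_report(c(1, 1, 2), c(1, 1, 2), K = 3)
  expect_equal(rep0$per_class$f1[3], 0)
  expect_true(rep0$per_class$flagged[3])

  set.seed(8)
  for (trial in 1:1000) {
    K <- sample(2:5, 1)
    n <- sample(3:40, 1)
    yt <- sample.int(K, n, TRUE); yp <- sample.int(K, n, TRUE)
    expect_equal(f1_report(yt, yp, K)$per_class$f1, bf_f1(yt, yp, K), tolerance = 1e-12)
  }
})

test_that("weight optimization concentrates on an accurate classifier and respects ties", {
  set.seed(30)
  K <- 4; n <- 200
  y <- sample.int(K, n, TRUE)
  folds <- rep(1:5, length.out = n)
  perfect <- matrix(0.02, n, K); perfect[cbind(1:n, y)] <- 0.94
  # adversaries that confidently agree on a wrong class
  wrong <- (y %% K) + 1
  adv <- matrix(0.1 / (K - 1), n, K); adv[cbind(1:n, wrong)] <- 0.9
  grid <- enumerate_weight_grid("scalar", n_classifiers = 3, n_classes = K)
  for (perfect_slot in c(1, 3)) {
    probs <- list(adv, adv)
    probs <- append(probs, list(perfect), after = perfect_slot - 1)
    opt <- optimize_weights(probs, y, folds, grid, K)
    expect_gte(opt$w[perfect_slot, 1], 0.5)
    expect_equal(opt$cv_macro_f1, 1)
  }
  noise1 <- matrix(runif(n * K), n); noise1 <- noise1 / rowSums(noise1)
  # grid of size one returns that matrix; identical classifiers return the first
  tiny <- grid; tiny$matrices <- grid$matrices[5]
  expect_equal(optimize_weights(list(noise1, noise1, noise1), y, folds, tiny, K)$w,
               grid$matrices[[5]])
  same <- optimize_weights(list(noise1, noise1, noise1), y, folds, grid, K)
  expect_equal(same$w, grid$matrices[[1]])
})

test_that("optimized weights never fall below the best single classifier on the grid", {
  set.seed(31)
  K <- 4; n <- 150
  y <- sample.int(K, n, TRUE)
  folds <- rep(1:5, length.out = n)
  probs <- lapply(1:3, function(i) {
    m <- matrix(runif(n * K), n); m <- m / rowSums(m)
    m[cbind(1:n, y)] <- m[cbind(1:n, y)] + 0.2 * i
    m / rowSums(m)
  })
  grid <- enumerate_weight_grid("scalar", n_classifiers = 3, n_classes = K)
  opt <- optimize_weights(probs, y, folds, grid, K)
  one_hots <- lapply(1:3, function(i) { w <- matrix(0, 3, K); w[i, ] <- 1; w })
  singles <- vapply(one_hots, netwell:::grid_macro_f1, numeric(1),
                    probs = probs, y = y, folds = folds, K = K)
  expect_gte(opt$cv_macro_f1, max(singles) - 1e-12)
})

test_that("random baseline converges to the closed form 2p/(Kp+1)", {
  set.seed(40)
  K <- 4
  y <- rep(1:4, times = c(25, 25, 25, 25))
  rb <- random_baseline(y, K, seed = 1, reps = 400)
  expect_equal(rb$closed_form, rep(2 * 0.25 / (K * 0.25 + 1), 4), tolerance = 1e-12)
  expect_equal(rb$per_class_f1, rb$closed_form, tolerance = 0.02)
  rb2 <- random_baseline(y, K, seed = 1, reps = 5)
  expect_equal(rb2$predictions, random_baseline(y, K, seed = 1, reps = 5)$predictions)
})

test_that("relative improvement rounds half away from zero and flags zero baselines", {
  expect_equal(relative_improvement(0.42, 0.58), 38L)
  expect_equal(relative_improvement(0.06, 0.43), 617L)
  expect_equal(relative_improvement(0.5, 0.5), 0L)
  # the half-away rule itself (0.43/0.40 hits 7.4999... in floating point,
  # so exercise the rounding on exact halves directly)
  expect_equal(netwell:::round_half_away(c(7.5, -7.5, 2.4, -2.4)),
               c(8L, -8L, 2L, -2L))
  expect_equal(relative_improvement(0.31, 0.51), 65L)  # 64.516 -> 65
  expect_warning(out <- relative_improvement(0, 0.5), "undefined")
  expect_true(is.na(out))
  expect_error(relative_improvement(-0.1, 0.5), "negative")
})

test_that("the full harness fits, votes and reports on synthetic data", {
  run <- cached_default_run()
  pred <- predict_wellness(run$features, "stress", "full", seed = 17,
                           grids = classifier_grids(fast = TRUE))
  expect_s3_class(pred, "netwell_prediction")
  expect_length(pred$selected, 3)
  expect_true(all(pred$weights >= 0) && abs(sum(pred$weights[, 1]) - 1) < 1e-9)
  expect_true(pred$f1$macro_f1 >= 0 && pred$f1$macro_f1 <= 1)
  expect_equal(length(pred$test_predictions), pred$n_test)
  # determinism of the whole harness
  pred2 <- predict_wellness(run$features, "stress", "full", seed = 17,
                            grids = classifier_grids(fast = TRUE))
  expect_equal(pred$f1$macro_f1, pred2$f1$macro_f1)
  expect_identical(pred$test_predictions, pred2$test_predictions)
})
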