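# Ordinal wellness-state prediction: participant-week feature assembly,
# grid-searched base classifiers (KNN, CART, SVM, LR, RF), and the
# weighted-voting ensemble y_vote = argmax_j sum_i w_ij * p_ij over the
# three best base classifiers.

CLASSIFIER_ORDER <- c("knn", "cart", "svm", "lr", "rf")

STRUCTURE_COLUMNS <- as.vector(outer(STRUCTURE_METRICS,
                                     c("participant", "whole"),
                                     function(m, v) paste(m, v, sep = "_")))

#' Merged participant-week feature table
#'
#' Joins the twelve weekly behavioral features, the ten structural features
#' (five metrics x two network variants, spread to columns named
#' `<metric>_<variant>`), the gender indicator (male = 1, female = 0,
#' unreported = NA) and the four wellness labels into one row per
#' participant-week.
#'
#' @param behavior table from [behavior_feature_table()].
#' @param structure table from [structural_feature_table()].
#' @param survey table from [read_survey()] or [generate_cohort()].
#' @return wide `data.table`.
#' @export
feature_table <- function(behavior, structure, survey) {
  str_wide <- data.table::dcast(
    data.table::as.data.table(structure),
    participant + week ~ variant,
    value.var = STRUCTURE_METRICS)
  # dcast names are <metric>_<variant>
  beh <- data.table::as.data.table(behavior)
  out <- merge(beh, str_wide, by = c("participant", "week"), all = TRUE)
  sv <- data.table::as.data.table(survey)
  sv <- sv[, c("participant", "gender", names(WELLNESS_RANGES)), with = FALSE]
  sv[, gender_bin := data.table::fifelse(gender == "male", 1L,
                                         data.table::fifelse(gender == "female", 0L, NA_integer_))]
  out <- merge(out, sv, by = "participant", all.x = TRUE)
  data.table::setorder(out, participant, week)
  out[]
}

feature_set_columns <- function(feature_set) {
  switch(feature_set,
         baseline = c("gender_bin", BEHAVIOR_FEATURES),
         network_only = STRUCTURE_COLUMNS,
         full = c("gender_bin", BEHAVIOR_FEATURES, STRUCTURE_COLUMNS),
         stop(sprintf("unknown feature set '%s'", feature_set), call. = FALSE))
}

#' Assemble a modelling dataset
#'
#' Restricts the merged feature table to one wellness attribute and one
#' feature set (`baseline` = gender + 12 behavioral, `network_only` = 10
#' structural, `full` = all 23), keeping only rows with a label and
#' complete features. Features are standardized later with training-split
#' statistics only (see [split_train_test()] / the prediction harness), not
#' here.
#'
#' @param table merged table from [feature_table()].
#' @param attribute one of `stress`, `happiness`, `positive_attitude`,
#'   `health`.
#' @param feature_set `"baseline"`, `"network_only"` or `"full"`.
#' @return list: `x` (numeric matrix), `y` (integer labels), `participant`,
#'   `week`, `n_classes`, `feature_set`, `attribute`, `n_dropped`.
#' @export
assemble_dataset <- function(table, attribute, feature_set = "full") {
  if (!attribute %in% names(WELLNESS_RANGES)) {
    stop(sprintf("unknown attribute '%s'", attribute), call. = FALSE)
  }
  cols <- feature_set_columns(feature_set)
  dt <- data.table::as.data.table(table)
  missing_cols <- setdiff(c(cols, attribute), names(dt))
  if (length(missing_cols)) {
    stop(sprintf("feature table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  y <- dt[[attribute]]
  x <- as.matrix(dt[, cols, with = FALSE])
  keep <- !is.na(y) & complete.cases(x)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no complete labelled rows to model", call. = FALSE)
  list(x = x[keep, , drop = FALSE], y = as.integer(y[keep]),
       participant = dt$participant[keep], week = dt$week[keep],
       n_classes = length(WELLNESS_RANGES[[attribute]]),
       feature_set = feature_set, attribute = attribute,
       n_dropped = n_dropped)
}

# Largest-remainder stratified sampling of `frac` of the units per class,
# totalling exactly floor(frac * n) units.
stratified_pick <- function(labels, frac) {
  n <- length(labels)
  target <- floor(frac * n)
  classes <- split(seq_len(n), labels)
  base <- vapply(classes, function(idx) floor(frac * length(idx)), numeric(1))
  rem <- vapply(classes, function(idx) frac * length(idx), numeric(1)) - base
  extra <- target - sum(base)
  if (extra > 0) {
    bump <- head(order(rem, decreasing = TRUE), extra)
    base[bump] <- base[bump] + 1
  }
  picked <- unlist(lapply(seq_along(classes), function(i) {
    idx <- classes[[i]]
    if (base[i] == 0) return(integer(0))
    idx[sample.int(length(idx), base[i])]
  }))
  sort(picked)
}

#' Split a dataset into training and test portions
#'
#' `unit = "participant"` (default) keeps all weeks of a participant on one
#' side, stratifying participants by label, which avoids leaking a
#' participant's weeks across the split; `unit = "row"` stratifies
#' individual participant-weeks. The training side receives
#' `floor(frac * n_units)` units (largest-remainder allocation across
#' classes).
#'
#' @param dataset list from [assemble_dataset()].
#' @param frac training fraction in `(0, 1)` (default 0.75).
#' @param unit `"participant"` or `"row"`.
#' @param seed integer seed.
#' @return list `train`, `test`, each shaped like the input dataset.
#' @export
split_train_test <- function(dataset, frac = 0.75, unit = c("participant", "row"),
                             seed = 1L) {
  unit <- match.arg(unit)
  if (frac <= 0 || frac >= 1) stop("`frac` must be in (0, 1)", call. = FALSE)
  set.seed(derive_seed(seed, "split"))
  if (unit == "row") {
    tr_rows <- stratified_pick(dataset$y, frac)
  } else {
    pt <- unique(data.table::data.table(participant = dataset$participant,
                                        y = dataset$y))
    pt <- pt[!duplicated(participant)]
    if (nrow(pt) < 2) stop("need at least 2 participants to split", call. = FALSE)
    tr_p <- pt$participant[stratified_pick(pt$y, frac)]
    tr_rows <- which(dataset$participant %in% tr_p)
  }
  if (length(tr_rows) == 0 || length(tr_rows) == length(dataset$y)) {
    stop("degenerate split: empty training or test side", call. = FALSE)
  }
  subset_ds <- function(rows) {
    out <- dataset
    out$x <- dataset$x[rows, , drop = FALSE]
    out$y <- dataset$y[rows]
    out$participant <- dataset$participant[rows]
    out$week <- dataset$week[rows]
    out
  }
  train <- subset_ds(tr_rows)
  test <- subset_ds(setdiff(seq_along(dataset$y), tr_rows))
  missing_train <- setdiff(seq_len(dataset$n_classes), unique(train$y))
  if (length(missing_train)) {
    warning(sprintf("class(es) %s absent from training split",
                    paste(missing_train, collapse = ", ")), call. = FALSE)
  }
  list(train = train, test = test)
}

# ---- feature scaling (training statistics only) -----------------------------

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$mu, scale = scaler$sd)
}

# ---- base classifiers -------------------------------------------------------

# Each fitter trains on (x, factor y restricted to observed classes) and
# each predictor returns an n x K probability matrix over ALL K classes
# (zero columns for classes unseen in training).

expand_probs <- function(p, observed_levels, K) {
  out <- matrix(0, nrow = nrow(p), ncol = K)
  out[, as.integer(observed_levels)] <- p
  # guard against all-zero rows (degenerate learners): fall back to uniform
  zero <- rowSums(out) == 0
  if (any(zero)) out[zero, ] <- 1 / K
  out / rowSums(out)
}

fit_base_classifier <- function(name, x, y, K, params) {
  yf <- factor(y, levels = sort(unique(y)))
  obs <- levels(yf)
  model <- switch(
    name,
    knn = caret::knn3(x, yf, k = min(params$k, nrow(x))),
    cart = rpart::rpart(y ~ ., data = data.frame(y = yf, x),
                        method = "class",
                        control = rpart::rpart.control(minbucket = params$minbucket,
                                                       cp = 0.001)),
    svm = e1071::svm(x, yf, kernel = params$kernel,
                     degree = params$degree %||% 3,
                     cost = params$cost %||% 1,
                     probability = TRUE, scale = FALSE),
    lr = nnet::multinom(y ~ ., data = data.frame(y = yf, x),
                        decay = params$decay, trace = FALSE,
                        MaxNWts = 5000),
    rf = randomForest::randomForest(x, yf, ntree = params$ntree),
    stop(sprintf("unknown classifier '%s'", name), call. = FALSE)
  )
  structure(list(name = name, model = model, observed = obs, K = K,
                 params = params), class = "netwell_classifier")
}

predict_probs <- function(fit, x) {
  obs <- fit$observed
  p <- switch(
    fit$name,
    knn = predict(fit$model, x, type = "prob"),
    cart = predict(fit$model, data.frame(x), type = "prob"),
    svm = {
      pr <- predict(fit$model, x, probability = TRUE)
      probs <- attr(pr, "probabilities")
      probs[, obs, drop = FALSE]
    },
    lr = {
      pr <- predict(fit$model, data.frame(x), type = "probs")
      if (is.null(dim(pr))) {
        # two observed classes: multinom returns P(second level)
        cbind(1 - pr, pr)
      } else {
        pr[, obs, drop = FALSE]
      }
    },
    rf = predict(fit$model, x, type = "prob")[, obs, drop = FALSE]
  )
  p <- as.matrix(p)
  expand_probs(p, obs, fit$K)
}

predict_class <- function(fit, x) {
  max.col(predict_probs(fit, x), ties.method = "first")
}

#' Hyper-parameter grids for the five base classifiers
#'
#' Defaults: number of neighbors for KNN; minimum leaf size for CART;
#' linear, polynomial (degrees 2-3) and RBF kernels with a small cost grid
#' for SVM; regularization decay for multinomial LR; and 10 to 100 trees in
#' steps of 5 for RF (19 values). `fast = TRUE` gives a reduced grid for
#' repeated simulation studies.
#'
#' @param fast reduced grids for repeated runs (default `FALSE`).
#' @return named list of per-classifier parameter grids (lists of parameter
#'   sets; `rf` is the vector of candidate tree counts).
#' @export
classifier_grids <- function(fast = FALSE) {
  if (fast) {
    return(list(
      knn = list(list(k = 5), list(k = 11)),
      cart = list(list(minbucket = 5)),
      svm = list(list(kernel = "linear", cost = 1),
                 list(kernel = "radial", cost = 1)),
      lr = list(list(decay = 0.1)),
      rf = seq(10, 100, by = 5)
    ))
  }
  list(
    knn = lapply(c(1, 3, 5, 7, 9, 11, 15, 21), function(k) list(k = k)),
    cart = lapply(c(1, 2, 5, 10, 20), function(m) list(minbucket = m)),
    svm = c(lapply(c(0.1, 1, 10), function(cc) list(kernel = "linear", cost = cc)),
            lapply(2:3, function(d) list(kernel = "polynomial", degree = d, cost = 1)),
            lapply(c(0.1, 1, 10), function(cc) list(kernel = "radial", cost = cc))),
    lr = lapply(c(0, 0.01, 0.1, 1), function(d) list(decay = d)),
    rf = seq(10, 100, by = 5)
  )
}

# Stratified fold assignment; folds shrink when a class has fewer members
# than n_folds.
make_folds <- function(y, n_folds, seed) {
  set.seed(derive_seed(seed, "folds"))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  fold
}

#' Tune the base classifiers by cross-validated grid search
#'
#' Runs stratified `n_folds`-fold cross-validation on the training data for
#' every parameter set of every base classifier, selects the
#' highest-mean-accuracy parameters per classifier, and refits each
#' classifier on the full training split. By default the RF tree count is
#' fixed at `rf_ntree_fixed = 35` (the reported protocol); pass `NULL` to
#' grid-search the tree counts in `grids$rf` instead. Features are
#' standardized with training statistics before fitting.
#'
#' @param train training dataset from [split_train_test()].
#' @param grids parameter grids, see [classifier_grids()].
#' @param n_folds CV folds (default 5; classes smaller than the fold count
#'   are spread as evenly as possible with a warning).
#' @param seed integer seed controlling fold assignment.
#' @param rf_ntree_fixed fixed RF tree count (default 35) or `NULL`.
#' @param classifiers which base classifiers to tune (default all five).
#' @return list of class `netwell_tuned`: `fits` (per-classifier fitted
#'   model, best params), `cv_accuracy` (named vector), `cv_table`, `scaler`,
#'   `folds`, `seed`.
#' @export
tune_base_classifiers <- function(train, grids = classifier_grids(),
                                  n_folds = 5L, seed = 1L,
                                  rf_ntree_fixed = 35L,
                                  classifiers = CLASSIFIER_ORDER) {
  if (length(train$y) == 0) stop("empty training data", call. = FALSE)
  K <- train$n_classes
  scaler <- fit_scaler(train$x)
  x <- apply_scaler(train$x, scaler)
  y <- train$y
  min_class <- min(table(y))
  if (min_class < n_folds) {
    warning(sprintf("smallest class has %d member(s) < %d folds; folds reduced for it",
                    min_class, n_folds), call. = FALSE)
  }
  folds <- make_folds(y, n_folds, seed)

  rf_grid <- if (is.null(rf_ntree_fixed)) {
    lapply(grids$rf, function(nt) list(ntree = nt))
  } else {
    list(list(ntree = as.integer(rf_ntree_fixed)))
  }
  param_grids <- list(knn = grids$knn, cart = grids$cart, svm = grids$svm,
                      lr = grids$lr, rf = rf_grid)[classifiers]

  cv_rows <- list()
  fits <- list()
  cv_accuracy <- numeric(0)
  for (name in classifiers) {
    grid <- param_grids[[name]]
    acc <- vapply(grid, function(params) {
      correct <- 0L
      for (f in sort(unique(folds))) {
        tr <- folds != f
        fit <- fit_base_classifier(name, x[tr, , drop = FALSE], y[tr], K, params)
        pred <- predict_class(fit, x[!tr, , drop = FALSE])
        correct <- correct + sum(pred == y[!tr])
      }
      correct / length(y)
    }, numeric(1))
    best <- which.max(acc)   # first-best in grid order on ties
    cv_rows[[name]] <- data.table::data.table(
      classifier = name,
      params = vapply(grid, function(p) paste(names(p), unlist(p), sep = "=",
                                              collapse = ","), character(1)),
      cv_accuracy = acc
    )
    fits[[name]] <- fit_base_classifier(name, x, y, K, grid[[best]])
    cv_accuracy[name] <- acc[best]
  }
  structure(list(fits = fits, cv_accuracy = cv_accuracy,
                 cv_table = data.table::rbindlist(cv_rows),
                 scaler = scaler, folds = folds, seed = seed, K = K),
            class = "netwell_tuned")
}

#' Select the three best base classifiers
#'
#' Highest mean cross-validation accuracy; ties broken by the fixed
#' classifier order knn, cart, svm, lr, rf.
#'
#' @param cv_accuracy named numeric vector of per-classifier mean CV
#'   accuracies (e.g. from [tune_base_classifiers()]).
#' @return character vector of three classifier names.
#' @export
select_top3 <- function(cv_accuracy) {
  if (length(cv_accuracy) < 3) stop("need at least 3 tuned classifiers", call. = FALSE)
  ord <- order(-cv_accuracy, match(names(cv_accuracy), CLASSIFIER_ORDER))
  names(cv_accuracy)[ord][1:3]
}

# Nonnegative integer compositions of `total` into `parts` parts.
compositions <- function(total, parts) {
  if (parts == 1) return(matrix(total, ncol = 1))
  out <- list()
  for (first in 0:total) {
    rest <- compositions(total - first, parts - 1)
    out[[first + 1]] <- cbind(first, rest)
  }
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  res
}

#' Enumerate the weight grid for the voting ensemble
#'
#' `scalar` mode: every weight matrix with one weight per classifier,
#' constant across classes, on the step-grid simplex over classifiers
#' (66 matrices for 3 classifiers at step 0.1). `per_class` mode: the
#' step-grid simplex rows over the K classes (each row sums to 1; 286 rows
#' for K = 4 at step 0.1), from which per-classifier rows are drawn -- the
#' full cross product over classifiers is combinatorially large and is
#' searched by coordinate ascent in [optimize_weights()] rather than
#' materialized.
#'
#' @param mode `"scalar"` or `"per_class"`.
#' @param step grid interval; `1/step` must be (near-)integer (default 0.1).
#' @param n_classifiers ensemble size (default 3).
#' @param n_classes number of classes K (default 4).
#' @return list of class `weight_grid` with `mode`, `step`, and either
#'   `matrices` (scalar: list of `n_classifiers x n_classes` matrices) or
#'   `rows` (per_class: simplex row matrix).
#' @export
enumerate_weight_grid <- function(mode = c("scalar", "per_class"), step = 0.1,
                                  n_classifiers = 3L, n_classes = 4L) {
  mode <- match.arg(mode)
  if (!is.numeric(step) || step <= 0 || step > 1) {
    stop("`step` must be in (0, 1]", call. = FALSE)
  }
  m <- round(1 / step)
  if (abs(m - 1 / step) > 1e-8) stop("`step` must divide 1 evenly", call. = FALSE)
  out <- list(mode = mode, step = step, n_classifiers = n_classifiers,
              n_classes = n_classes)
  if (mode == "scalar") {
    comp <- compositions(m, n_classifiers) / m
    out$matrices <- lapply(seq_len(nrow(comp)), function(i) {
      matrix(rep(comp[i, ], n_classes), nrow = n_classifiers, ncol = n_classes)
    })
  } else {
    out$rows <- compositions(m, n_classes) / m
  }
  structure(out, class = "weight_grid")
}

#' Weighted-voting ensemble prediction
#'
#' `y_vote = argmax_j sum_i w_ij * p_ij`; ties resolve to the lowest class
#' index. `p` may be one instance's `n_classifiers x K` probability matrix
#' (returns one label) or a list of per-classifier `n x K` matrices
#' (returns `n` labels).
#'
#' @param p probability matrix or list of per-classifier matrices.
#' @param w `n_classifiers x K` weight matrix.
#' @return integer class label(s).
#' @export
ensemble_vote <- function(p, w) {
  if (is.list(p)) {
    if (length(p) != nrow(w) || any(vapply(p, ncol, 1L) != ncol(w))) {
      stop("probability/weight dimension mismatch", call. = FALSE)
    }
    scores <- Reduce(`+`, lapply(seq_along(p), function(i) {
      p[[i]] * matrix(w[i, ], nrow = nrow(p[[i]]), ncol = ncol(w), byrow = TRUE)
    }))
    return(max.col(scores, ties.method = "first"))
  }
  if (!all(dim(p) == dim(w))) stop("probability/weight dimension mismatch", call. = FALSE)
  scores <- colSums(p * w)
  which.max(scores)   # which.max takes the first (lowest) index on ties
}

#' Per-class and averaged F1 report
#'
#' Per-class F1 = `2PR/(P+R)` with the zero rule (0 when `P + R = 0`);
#' `macro_f1` is the unweighted mean over the K classes and `weighted_f1`
#' the support-weighted mean over classes present in `y_true`.
#'
#' @param y_true,y_pred integer labels in `1..K`.
#' @param K number of classes.
#' @return list: `per_class` (data.table: class, precision, recall, f1,
#'   support, flagged for classes absent from both vectors), `macro_f1`,
#'   `weighted_f1`, `accuracy`.
#' @export
f1_report <- function(y_true, y_pred, K) {
  if (length(y_true) != length(y_pred)) stop("label lengths differ", call. = FALSE)
  if (any(c(y_true, y_pred) < 1 | c(y_true, y_pred) > K)) {
    stop("labels outside 1..K", call. = FALSE)
  }
  per <- data.table::data.table(class = seq_len(K))
  per[, `:=`(
    tp = vapply(class, function(k) sum(y_true == k & y_pred == k), numeric(1)),
    pred_n = vapply(class, function(k) sum(y_pred == k), numeric(1)),
    support = vapply(class, function(k) sum(y_true == k), numeric(1))
  )]
  per[, precision := data.table::fifelse(pred_n > 0, tp / pred_n, 0)]
  per[, recall := data.table::fifelse(support > 0, tp / support, 0)]
  per[, f1 := data.table::fifelse(precision + recall > 0,
                                  2 * precision * recall / (precision + recall), 0)]
  per[, flagged := support == 0 & pred_n == 0]
  macro <- mean(per$f1)
  present <- per[support > 0]
  weighted <- sum(present$f1 * present$support) / sum(present$support)
  list(per_class = per[, .(class, precision, recall, f1, support, flagged)],
       macro_f1 = macro, weighted_f1 = weighted,
       accuracy = mean(y_true == y_pred))
}

# Out-of-fold probability matrices of the selected classifiers on the
# (scaled) training data, for weight optimization.
oof_probabilities <- function(x, y, K, fits, folds) {
  probs <- lapply(fits, function(f) matrix(NA_real_, nrow = length(y), ncol = K))
  names(probs) <- names(fits)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    for (name in names(fits)) {
      fit <- fit_base_classifier(name, x[tr, , drop = FALSE], y[tr], K,
                                 fits[[name]]$params)
      probs[[name]][!tr, ] <- predict_probs(fit, x[!tr, , drop = FALSE])
    }
  }
  probs
}

grid_macro_f1 <- function(w, probs, y, folds, K) {
  f1s <- vapply(sort(unique(folds)), function(f) {
    idx <- folds == f
    votes <- ensemble_vote(lapply(probs, function(p) p[idx, , drop = FALSE]), w)
    f1_report(y[idx], votes, K)$macro_f1
  }, numeric(1))
  mean(f1s)
}

#' Optimize ensemble weights on cross-validated training predictions
#'
#' Evaluates candidate weight matrices by the mean across folds of the
#' macro-F1 of [ensemble_vote()] on each held-out fold's out-of-fold
#' probabilities, returning the first grid point attaining the maximum (in
#' enumeration order). For `per_class` grids the per-classifier simplex
#' rows are searched by coordinate ascent (one classifier's row at a time,
#' repeated until no improvement), since the full cross product is
#' combinatorially large.
#'
#' @param probs list of per-classifier out-of-fold `n x K` probability
#'   matrices (see [oof_probabilities()] via the harness).
#' @param y training labels.
#' @param folds fold assignment used to produce `probs`.
#' @param grid a [enumerate_weight_grid()] object.
#' @param K number of classes.
#' @return list: `w` (weight matrix), `cv_macro_f1`.
#' @export
optimize_weights <- function(probs, y, folds, grid, K) {
  if (grid$mode == "scalar") {
    if (length(grid$matrices) == 0) stop("empty weight grid", call. = FALSE)
    best_w <- NULL
    best_f1 <- -Inf
    for (w in grid$matrices) {
      f1 <- grid_macro_f1(w, probs, y, folds, K)
      if (f1 > best_f1) {
        best_f1 <- f1
        best_w <- w
      }
    }
    return(list(w = best_w, cv_macro_f1 = best_f1))
  }
  # per_class: coordinate ascent over simplex rows
  n_cls <- length(probs)
  rows <- grid$rows
  w <- matrix(1 / K, nrow = n_cls, ncol = K)
  best_f1 <- grid_macro_f1(w, probs, y, folds, K)
  for (sweep in seq_len(10)) {
    improved <- FALSE
    for (i in seq_len(n_cls)) {
      for (ri in seq_len(nrow(rows))) {
        cand <- w
        cand[i, ] <- rows[ri, ]
        f1 <- grid_macro_f1(cand, probs, y, folds, K)
        if (f1 > best_f1 + 1e-12) {
          best_f1 <- f1
          w <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(w = w, cv_macro_f1 = best_f1)
}

#' Uniform-random prediction baseline
#'
#' Draws i.i.d. uniform class labels for the test set, repeated `reps`
#' times; reports the Monte-Carlo mean per-class and macro F1 together with
#' the closed-form expectation `2p/(Kp+1)` for a class of prevalence `p`.
#'
#' @param y_test integer test labels in `1..K`.
#' @param K number of classes.
#' @param seed integer seed.
#' @param reps Monte-Carlo repetitions (default 1000).
#' @return list: `per_class_f1` (MC means), `macro_f1`, `per_class_se`
#'   (MC standard errors), `closed_form` (per-class expectation),
#'   `predictions` (first repetition's draws).
#' @export
random_baseline <- function(y_test, K, seed = 1L, reps = 1000L) {
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  set.seed(derive_seed(seed, "random_baseline"))
  n <- length(y_test)
  per_class <- matrix(0, nrow = reps, ncol = K)
  macro <- numeric(reps)
  first <- NULL
  for (r in seq_len(reps)) {
    pred <- sample.int(K, n, replace = TRUE)
    if (r == 1) first <- pred
    rep_f1 <- f1_report(y_test, pred, K)
    per_class[r, ] <- rep_f1$per_class$f1
    macro[r] <- rep_f1$macro_f1
  }
  p <- vapply(seq_len(K), function(k) mean(y_test == k), numeric(1))
  list(per_class_f1 = colMeans(per_class), macro_f1 = mean(macro),
       per_class_se = apply(per_class, 2, sd) / sqrt(reps),
       closed_form = 2 * p / (K * p + 1), predictions = first)
}

#' Relative improvement percentage
#'
#' `round(100 * (f1_full - f1_base) / f1_base)` to the nearest integer,
#' halves away from zero. Undefined (NA, with a warning) when the baseline
#' is zero.
#'
#' @param f1_base,f1_full baseline and comparison scores (`f1_base >= 0`).
#' @return integer percentage.
#' @export
relative_improvement <- function(f1_base, f1_full) {
  if (any(f1_base < 0)) stop("negative baseline score", call. = FALSE)
  out <- rep(NA_integer_, length(f1_base))
  zero <- f1_base == 0
  if (any(zero)) {
    warning("relative improvement undefined for zero baseline", call. = FALSE)
  }
  out[!zero] <- round_half_away(100 * (f1_full[!zero] - f1_base[!zero]) / f1_base[!zero])
  out
}

#' Fit and evaluate the weighted-voting wellness predictor
#'
#' The full harness for one attribute and one feature set: assemble the
#' dataset, split train/test, tune the base classifiers, select the three
#' with highest CV accuracy, optimize the voting weights on out-of-fold
#' training probabilities, and report test-set F1 for the ensemble.
#'
#' @param table merged feature table from [feature_table()].
#' @param attribute wellness attribute name.
#' @param feature_set `"baseline"`, `"network_only"` or `"full"`.
#' @param seed integer seed (split, folds, weight search).
#' @param frac training fraction (default 0.75).
#' @param unit split unit (default `"participant"`).
#' @param grids classifier grids (default [classifier_grids()]).
#' @param weight_mode `"scalar"` (default) or `"per_class"`.
#' @param n_folds CV folds (default 5).
#' @param classifiers base classifiers to tune (default all five).
#' @param rf_ntree_fixed fixed RF tree count (default 35) or `NULL` to tune.
#' @return list of class `netwell_prediction`: `f1` (test report), `selected`,
#'   `weights`, `cv_accuracy`, `test_predictions`, `test_labels`, plus the
#'   split sizes.
#' @export
predict_wellness <- function(table, attribute, feature_set = "full", seed = 1L,
                             frac = 0.75, unit = "participant",
                             grids = classifier_grids(),
                             weight_mode = "scalar", n_folds = 5L,
                             classifiers = CLASSIFIER_ORDER,
                             rf_ntree_fixed = 35L) {
  ds <- assemble_dataset(table, attribute, feature_set)
  sp <- split_train_test(ds, frac = frac, unit = unit, seed = seed)
  tuned <- tune_base_classifiers(sp$train, grids = grids, n_folds = n_folds,
                                 seed = seed, rf_ntree_fixed = rf_ntree_fixed,
                                 classifiers = classifiers)
  selected <- select_top3(tuned$cv_accuracy)
  K <- ds$n_classes

  x_train <- apply_scaler(sp$train$x, tuned$scaler)
  x_test <- apply_scaler(sp$test$x, tuned$scaler)
  probs_oof <- oof_probabilities(x_train, sp$train$y, K,
                                 tuned$fits[selected], tuned$folds)
  grid <- enumerate_weight_grid(weight_mode, step = 0.1,
                                n_classifiers = length(selected), n_classes = K)
  opt <- optimize_weights(probs_oof, sp$train$y, tuned$folds, grid, K)

  probs_test <- lapply(tuned$fits[selected], predict_probs, x = x_test)
  votes <- ensemble_vote(probs_test, opt$w)
  report <- f1_report(sp$test$y, votes, K)

  structure(list(
    attribute = attribute, feature_set = feature_set,
    f1 = report, selected = selected, weights = opt$w,
    cv_weight_macro_f1 = opt$cv_macro_f1,
    cv_accuracy = tuned$cv_accuracy,
    test_predictions = votes, test_labels = sp$test$y,
    n_train = length(sp$train$y), n_test = length(sp$test$y),
    seed = seed
  ), class = "netwell_prediction")
}

#' @export
print.netwell_prediction <- function(x, ...) {
  cat(sprintf("<netwell_prediction> %s / %s\n", x$attribute, x$feature_set))
  cat(sprintf("  ensemble : %s\n", paste(x$selected, collapse = " + ")))
  cat(sprintf("  macro F1 : %.3f (train %d / test %d rows)\n",
              x$f1$macro_f1, x$n_train, x$n_test))
  invisible(x)
}
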