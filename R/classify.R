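#' Subject-wise train/test split scheme
#'
#' Samples `n_splits` distinct test-subject sets of size `test_n` uniformly
#' without replacement from all `choose(n, test_n)` possibilities; the
#' remaining subjects form the training set. With 14 subjects and
#' `test_n = 3` this is the 80/20 scheme (11 train / 3 test) drawn from 364
#' possible test sets. Deterministic given `seed`.
#'
#' @param subject_ids character vector of subject labels.
#' @param n_splits number of splits (default 30).
#' @param test_n held-out subjects per split (default 3).
#' @param seed RNG seed.
#' @return Object of class `split_scheme`: list of `list(train, test)` with
#'   attributes `n_splits`, `test_n`, `seed`.
#' @export
make_splits <- function(subject_ids, n_splits = 30, test_n = 3, seed = 1) {
  subject_ids <- unique(subject_ids)
  all_tests <- combn(subject_ids, test_n, simplify = FALSE)
  if (n_splits > length(all_tests)) {
    stop(sprintf("n_splits = %d exceeds the %d distinct test sets available",
                 n_splits, length(all_tests)))
  }
  picked <- run_with_seed(seed, sample.int(length(all_tests), n_splits))
  splits <- lapply(all_tests[picked], function(te) {
    list(train = setdiff(subject_ids, te), test = te)
  })
  structure(splits, class = "split_scheme",
            n_splits = n_splits, test_n = test_n, seed = seed)
}

#' Hyperparameter grid for the gradient-boosted classifier
#'
#' The full grid crosses learning rates 0.005/0.01/0.05/0.1/0.15, ensemble
#' sizes 250-1500 in steps of 250, and tree depths 3-7 (150 combinations).
#' `grid_mode = "reduced"` uses a fixed 3-combination subset of that grid
#' for fast runs; the full grid is opt-in because of its compute cost.
#'
#' @param grid_mode `"reduced"` (default) or `"full"`.
#' @param cv_folds inner cross-validation folds (default 5, subject-grouped).
#' @return Object of class `classifier_config` with elements `grid` (data
#'   frame of `learning_rate`, `n_estimators`, `max_depth`), `cv_folds`,
#'   `grid_mode`.
#' @export
classifier_config <- function(grid_mode = c("reduced", "full"), cv_folds = 5) {
  grid_mode <- match.arg(grid_mode)
  full <- expand.grid(
    learning_rate = c(0.005, 0.01, 0.05, 0.1, 0.15),
    n_estimators = c(250, 500, 750, 1000, 1250, 1500),
    max_depth = 3:7,
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- if (grid_mode == "full") {
    full
  } else {
    data.frame(learning_rate = c(0.1, 0.05, 0.1),
               n_estimators = c(250, 250, 500),
               max_depth = c(3, 3, 3))
  }
  structure(list(grid = grid, cv_folds = cv_folds, grid_mode = grid_mode),
            class = "classifier_config")
}

stage_to_int <- function(stage) {
  as.integer(factor(stage, levels = stage_levels())) - 1L
}

fit_gbc <- function(X, y_int, hp, seed = 1) {
  dtr <- xgboost::xgb.DMatrix(X, label = y_int)
  xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = 4,
                  eta = hp$learning_rate, max_depth = hp$max_depth,
                  nthread = 1, seed = as.integer(seed)),
    data = dtr, nrounds = hp$n_estimators, verbose = 0
  )
}

predict_gbc <- function(model, X) {
  prob <- predict(model, xgboost::xgb.DMatrix(X))
  prob <- matrix(prob, ncol = 4, byrow = FALSE)
  stage_levels()[max.col(prob, ties.method = "first")]
}

# Round-robin assignment of shuffled subjects to cv folds.
group_folds <- function(subjects, k, seed = 1) {
  u <- run_with_seed(seed, sample(unique(subjects)))
  fold_of <- rep(seq_len(k), length.out = length(u))
  names(fold_of) <- u
  fold_of[subjects]
}

#' Subject-grouped grid search
#'
#' Evaluates every hyperparameter combination of the grid by k-fold
#' cross-validation in which folds are formed at the subject level (no
#' subject contributes epochs to both the fit and validation side of a
#' fold), and returns the combination with the highest mean validation
#' accuracy. Ties are broken toward the cheapest model: smaller ensemble,
#' then shallower trees, then smaller learning rate.
#'
#' @param X numeric feature matrix (epochs x features).
#' @param stage character vector of epoch stage labels.
#' @param subjects character vector of epoch subject ids (>= 2 distinct).
#' @param config a [classifier_config()].
#' @param seed RNG seed for fold assignment.
#' @return One-row data frame `learning_rate`, `n_estimators`, `max_depth`
#'   with attribute `cv_accuracy`.
#' @export
grid_search <- function(X, stage, subjects, config = classifier_config(), seed = 1) {
  if (length(unique(subjects)) < 2) stop("grid search needs >= 2 training subjects")
  if (length(unique(stage)) < 2) stop("degenerate single-class training data")
  y <- stage_to_int(stage)
  k <- min(config$cv_folds, length(unique(subjects)))
  folds <- group_folds(subjects, k, seed = seed)
  grid <- config$grid
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    hp <- grid[g, ]
    fold_acc <- vapply(seq_len(k), function(f) {
      tr <- folds != f; va <- folds == f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      model <- fit_gbc(X[tr, , drop = FALSE], y[tr], hp, seed = seed)
      mean(predict_gbc(model, X[va, , drop = FALSE]) == stage[va])
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  }, numeric(1))
  o <- order(-acc, grid$n_estimators, grid$max_depth, grid$learning_rate)
  best <- grid[o[1], , drop = FALSE]
  rownames(best) <- NULL
  attr(best, "cv_accuracy") <- acc[o[1]]
  best
}

#' Fit one subject-wise split and evaluate on its held-out subjects
#'
#' Fits a gradient-boosted tree ensemble on all training-subject epochs and
#' predicts every epoch of the held-out subjects. Training and test subject
#' sets must be disjoint and training data must contain all four stages.
#'
#' @param X epochs x features matrix with column names (feature schema).
#' @param meta data frame with `subject` and `stage` per row of `X`.
#' @param split `list(train, test)` of subject ids.
#' @param hyperparams one-row data frame (`learning_rate`, `n_estimators`,
#'   `max_depth`), e.g. from [grid_search()].
#' @param split_index bookkeeping index stored in the result.
#' @param expected_n_features if non-`NULL`, `ncol(X)` must match exactly
#'   (schema guard; 1740 for 30-channel connectivity features).
#' @param seed RNG seed passed to the learner.
#' @return Object of class `classifier_run`: `metric` (`NA`, filled by
#'   callers), `split_index`, `best_hyperparams`, `accuracy`, `confusion`
#'   (4 x 4 counts, rows = true stage), `importances` (per-feature gain
#'   shares, nonnegative, summing to 1).
#' @export
fit_evaluate <- function(X, meta, split, hyperparams, split_index = NA_integer_,
                         expected_n_features = NULL, seed = 1) {
  if (length(intersect(split$train, split$test)) > 0) {
    stop("train and test subject sets overlap")
  }
  if (!is.null(expected_n_features) && ncol(X) != expected_n_features) {
    stop(sprintf("feature length %d does not match the expected schema of %d",
                 ncol(X), expected_n_features))
  }
  tr <- meta$subject %in% split$train
  te <- meta$subject %in% split$test
  if (!all(stage_levels() %in% meta$stage[tr])) {
    stop("training data must contain all four stages")
  }
  model <- fit_gbc(X[tr, , drop = FALSE], stage_to_int(meta$stage[tr]),
                   hyperparams, seed = seed)
  pred <- predict_gbc(model, X[te, , drop = FALSE])
  truth <- factor(meta$stage[te], levels = stage_levels())
  confusion <- table(truth, factor(pred, levels = stage_levels()))
  confusion <- matrix(confusion, 4, 4,
                      dimnames = list(true = stage_levels(),
                                      predicted = stage_levels()))
  imp_tab <- xgboost::xgb.importance(model = model)
  imp <- stats::setNames(numeric(ncol(X)), colnames(X))
  imp[imp_tab$Feature] <- imp_tab$Gain
  if (sum(imp) > 0) imp <- imp / sum(imp)
  structure(
    list(metric = NA_character_, split_index = split_index,
         best_hyperparams = hyperparams,
         accuracy = mean(pred == meta$stage[te]),
         confusion = confusion, importances = imp),
    class = "classifier_run"
  )
}

#' Run the split scheme for one feature set
#'
#' For each subject-wise split: grid-search hyperparameters on the training
#' subjects (subject-grouped CV), refit on all training epochs and evaluate
#' on the held-out subjects. `metric = "power"` uses the band-power baseline
#' features instead of connectivity coefficients.
#'
#' @param fc an `fc_features` object.
#' @param metric one of the connectivity metrics in `fc`, or `"power"`.
#' @param splits a [make_splits()] scheme (built from `fc`'s subjects if
#'   `NULL`).
#' @param config a [classifier_config()].
#' @param seed RNG seed (folds and learner).
#' @return List of `classifier_run` objects, one per split.
#' @export
run_classification <- function(fc, metric = "PLV", splits = NULL,
                               config = classifier_config(), seed = 1) {
  X <- if (identical(metric, "power")) fc$power else fc$features[[metric]]
  if (is.null(X)) stop(sprintf("no features for metric '%s'", metric))
  expected <- if (identical(metric, "power")) {
    length(fc$band_names) * fc$n_channels
  } else {
    length(fc$band_names) * choose(fc$n_channels, 2)
  }
  if (is.null(splits)) {
    splits <- make_splits(unique(fc$meta$subject), seed = seed)
  }
  lapply(seq_along(splits), function(s) {
    sp <- splits[[s]]
    tr <- fc$meta$subject %in% sp$train
    hp <- grid_search(X[tr, , drop = FALSE], fc$meta$stage[tr],
                      fc$meta$subject[tr], config = config, seed = seed + s)
    run <- fit_evaluate(X, fc$meta, sp, hp, split_index = s,
                        expected_n_features = expected, seed = seed + s)
    run$metric <- metric
    run
  })
}

#' Aggregate classifier runs of one metric
#'
#' @param runs list of `classifier_run`s with identical feature schemas.
#' @return List with `mean_accuracy`, `accuracies` (per split), `confusion`
#'   (element-wise mean of the 4 x 4 count matrices), `importances` (mean,
#'   renormalised to sum to 1) and `band_share` (summed importance per
#'   frequency band, from the feature-name prefixes).
#' @export
aggregate_runs <- function(runs) {
  if (length(runs) == 0) stop("no runs supplied (0 of the expected runs present)")
  schemas <- vapply(runs, function(r) length(r$importances), integer(1))
  if (length(unique(schemas)) != 1) stop("runs have mismatched feature schemas")
  acc <- vapply(runs, `[[`, numeric(1), "accuracy")
  conf <- Reduce(`+`, lapply(runs, `[[`, "confusion")) / length(runs)
  imp <- Reduce(`+`, lapply(runs, `[[`, "importances")) / length(runs)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  band <- sub("_.*$", "", names(imp))
  band_share <- vapply(split(imp, band), sum, numeric(1))
  list(mean_accuracy = mean(acc), accuracies = acc, confusion = conf,
       importances = imp,
       band_share = band_share[order(match(names(band_share), band_definitions()$name))])
}

#' Compare classification accuracy across metrics
#'
#' One-way ANOVA of per-split accuracies across the metrics (columns),
#' followed by Tukey HSD all-pairs comparisons.
#'
#' @param accuracy_table numeric splits x metrics matrix with column names,
#'   no missing cells.
#' @return List with `F` (omnibus F statistic), `df` (numerator,
#'   denominator), `p`, and `tukey` (symmetric metrics x metrics matrix of
#'   adjusted p-values with unit diagonal).
#' @export
compare_metrics <- function(accuracy_table) {
  accuracy_table <- as.matrix(accuracy_table)
  if (any(!is.finite(accuracy_table))) stop("accuracy table has missing cells")
  long <- data.frame(
    accuracy = as.vector(accuracy_table),
    metric = factor(rep(colnames(accuracy_table), each = nrow(accuracy_table)))
  )
  fit <- aov(accuracy ~ metric, data = long)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$metric
  k <- ncol(accuracy_table)
  P <- matrix(1, k, k, dimnames = list(colnames(accuracy_table),
                                       colnames(accuracy_table)))
  for (r in rownames(tk)) {
    ab <- strsplit(r, "-", fixed = TRUE)[[1]]
    P[ab[1], ab[2]] <- P[ab[2], ab[1]] <- tk[r, "p adj"]
  }
  list(F = s$`F value`[1], df = s$Df, p = s$`Pr(>F)`[1], tukey = P)
}
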