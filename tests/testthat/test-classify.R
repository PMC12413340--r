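test_that("split schemes are distinct, subject-disjoint and deterministic", {
  ids <- paste0("s", 1:14)
  sch <- make_splits(ids, n_splits = 30, test_n = 3, seed = 4)
  expect_length(sch, 30)
  for (sp in sch) {
    expect_length(sp$train, 11)
    expect_length(sp$test, 3)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), ids)
  }
  keys <- vapply(sch, function(sp) paste(sort(sp$test), collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0)
  expect_identical(make_splits(ids, 30, 3, seed = 4), sch)

  # 4 subjects, test_n = 1, 4 splits: exactly the leave-one-out scheme
  loo <- make_splits(paste0("s", 1:4), n_splits = 4, test_n = 1, seed = 1)
  expect_setequal(vapply(loo, function(sp) sp$test, ""), paste0("s", 1:4))

  expect_error(make_splits(paste0("s", 1:4), n_splits = 5, test_n = 1, seed = 1),
               "exceeds")
})

test_that("the hyperparameter grid matches the published search space", {
  full <- classifier_config("full")
  expect_equal(nrow(full$grid), 150)
  expect_setequal(unique(full$grid$learning_rate), c(0.005, 0.01, 0.05, 0.1, 0.15))
  expect_setequal(unique(full$grid$n_estimators), c(250, 500, 750, 1000, 1250, 1500))
  expect_setequal(unique(full$grid$max_depth), 3:7)
  expect_equal(full$cv_folds, 5)

  red <- classifier_config("reduced")
  expect_equal(nrow(red$grid), 3)
  # reduced combinations are a subset of the full grid
  expect_true(all(apply(red$grid, 1, function(r) {
    any(apply(full$grid, 1, function(f) all(f == r)))
  })))
})

# Separable toy features: stage encoded exactly in the first column (zero
# within-class spread, so tree splits generalise to held-out subjects).
toy_features <- function(n_subjects = 6, n_epochs = 4, noise = 0, seed = 1) {
  meta <- expand.grid(epoch = seq_len(n_epochs), stage = stage_levels(),
                      subject = paste0("s", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)[, c("subject", "stage", "epoch")]
  X <- run_with_seed_test(seed, {
    cbind(10 * match(meta$stage, stage_levels()) + rnorm(nrow(meta), 0, noise),
          matrix(rnorm(nrow(meta) * 5), nrow(meta)))
  })
  colnames(X) <- paste0("delta_f", seq_len(ncol(X)))
  list(X = X, meta = meta)
}

test_that("grid search picks the cheapest of the tied best models", {
  toy <- toy_features()
  best <- grid_search(toy$X, toy$meta$stage, toy$meta$subject,
                      classifier_config("reduced"), seed = 2)
  expect_equal(attr(best, "cv_accuracy"), 1)
  # separable data: many combos tie at 1; tie-break yields the smallest
  expect_equal(best$n_estimators, 250)
  expect_equal(best$max_depth, 3)

  one <- classifier_config("reduced")
  one$grid <- one$grid[2, , drop = FALSE]
  best1 <- grid_search(toy$X, toy$meta$stage, toy$meta$subject, one, seed = 2)
  expect_equal(best1$learning_rate, one$grid$learning_rate)

  expect_error(grid_search(toy$X, rep("W", nrow(toy$X)), toy$meta$subject,
                           classifier_config("reduced")), "single-class")
  expect_error(grid_search(toy$X, toy$meta$stage, rep("s1", nrow(toy$X)),
                           classifier_config("reduced")), ">= 2")
})

test_that("fit_evaluate honours the subject-wise contract", {
  toy <- toy_features()
  hp <- data.frame(learning_rate = 0.1, n_estimators = 50, max_depth = 3)
  split <- list(train = paste0("s", 1:4), test = paste0("s", 5:6))
  run <- fit_evaluate(toy$X, toy$meta, split, hp, split_index = 1)
  expect_equal(run$accuracy, 1)
  expect_equal(sum(diag(run$confusion)) / sum(run$confusion), run$accuracy)
  # confusion row sums equal the per-stage test epoch counts
  expect_equal(unname(rowSums(run$confusion)), rep(8, 4))
  expect_equal(sum(run$importances), 1, tolerance = 1e-6)
  expect_true(all(run$importances >= 0))

  expect_error(fit_evaluate(toy$X, toy$meta,
                            list(train = paste0("s", 1:4), test = c("s4", "s5")),
                            hp), "overlap")
  expect_error(fit_evaluate(toy$X, toy$meta, split, hp,
                            expected_n_features = 1740), "schema")
  # missing stage in training data
  drop <- toy$meta$stage != "N3" | !(toy$meta$subject %in% split$train)
  expect_error(fit_evaluate(toy$X[drop, ], toy$meta[drop, ], split, hp),
               "all four stages")
})

test_that("classifier runs are reproducible under fixed seeds", {
  toy <- toy_features(noise = 15)          # non-trivial problem
  hp <- data.frame(learning_rate = 0.1, n_estimators = 50, max_depth = 3)
  split <- list(train = paste0("s", 1:4), test = paste0("s", 5:6))
  r1 <- fit_evaluate(toy$X, toy$meta, split, hp, seed = 5)
  r2 <- fit_evaluate(toy$X, toy$meta, split, hp, seed = 5)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$importances, r2$importances)
})

test_that("aggregation averages runs and splits importances by band", {
  toy <- toy_features()
  hp <- data.frame(learning_rate = 0.1, n_estimators = 50, max_depth = 3)
  split <- list(train = paste0("s", 1:4), test = paste0("s", 5:6))
  run <- fit_evaluate(toy$X, toy$meta, split, hp)
  agg1 <- aggregate_runs(list(run, run, run))
  expect_equal(agg1$mean_accuracy, run$accuracy)
  expect_equal(agg1$confusion, run$confusion)
  expect_equal(agg1$importances, run$importances)
  expect_equal(sum(agg1$band_share), 1, tolerance = 1e-6)
  expect_error(aggregate_runs(list()), "no runs")

  short <- run; short$importances <- run$importances[1:3]
  expect_error(aggregate_runs(list(run, short)), "mismatched")
})

test_that("metric comparison reduces to one-way ANOVA with Tukey HSD", {
  base <- run_with_seed_test(21, matrix(rnorm(30 * 6, 0.6, 0.05), 30, 6))
  colnames(base) <- metric_names()

  flat <- base
  for (k in 2:6) flat[, k] <- flat[, 1]    # identical columns
  res <- compare_metrics(flat)
  expect_equal(res$F, 0, tolerance = 1e-10)

  shifted <- base
  shifted[, "PLV"] <- shifted[, "PLV"] + 0.3
  res2 <- compare_metrics(shifted)
  expect_lt(res2$p, 0.001)
  expect_lt(res2$tukey["PLV", "COH"], 0.001)
  expect_gt(res2$tukey["COH", "iCOH"], 0.05)
  expect_identical(res2$tukey, t(res2$tukey))

  res3 <- compare_metrics(shifted[sample(30), ])
  expect_equal(res3$F, res2$F)

  shifted[3, 2] <- NA
  expect_error(compare_metrics(shifted), "missing cells")
})

test_that("power-feature classification follows the 120-feature schema", {
  fc <- contrast_features()
  spec_np <- length(fc$band_names) * fc$n_channels
  expect_equal(ncol(fc$power), spec_np)
  # schema guard distinguishes power from connectivity features
  hp <- data.frame(learning_rate = 0.1, n_estimators = 50, max_depth = 3)
  split <- list(train = paste0("s", 1:6), test = paste0("s", 7:8))
  expect_error(
    fit_evaluate(fc$power, fc$meta, split, hp,
                 expected_n_features = ncol(fc$features$PLV)),
    "schema"
  )
  run <- fit_evaluate(fc$power, fc$meta, split, hp,
                      expected_n_features = spec_np)
  expect_gt(run$accuracy, 0.25)            # power carries stage information
})
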