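test_that("CV RMSE is seeded-deterministic and validates folds", {
  tab <- make_table(n = 60, p = 4, support = 1, effects = 3, noise = 0.2)
  v1 <- hofd_cv_rmse(tab$X, tab$y, folds = 5, seed = 3)
  v2 <- hofd_cv_rmse(tab$X, tab$y, folds = 5, seed = 3)
  expect_identical(as.numeric(v1), as.numeric(v2))
  expect_length(attr(v1, "folds"), 5)

  expect_error(hofd_cv_rmse(tab$X[1:4, ], tab$y[1:4], folds = 5),
               class = "invalid_input")
  expect_error(hofd_cv_rmse(tab$X, tab$y, folds = 1), class = "invalid_input")
})

test_that("a perfectly predictable response yields near-zero CV RMSE", {
  set.seed(31)
  X <- matrix(runif(40), 40, 1)
  y <- 2 * X[, 1]
  v <- hofd_cv_rmse(X, y, folds = 4, seed = 1,
                    gp_opts = list(restarts = 1, maxit = 100))
  expect_lt(as.numeric(v), 0.05 * sd(y))
})

test_that("the decided subset attains the minimum of the RMSE curve", {
  tab <- make_table(n = 150, p = 6, support = c(1, 2), effects = c(3, 2),
                    noise = 0.3, seed = 9)
  cfg <- hofd_config(hybrid_mode = 1, start_size = 6, seed = 5)
  res <- hofd_select(tab$X, tab$y, cfg)
  expect_equal(min(res$rmse_curve$cv_rmse),
               res$rmse_curve$cv_rmse[res$rmse_curve$subset_size ==
                                      res$best_size])
  expect_identical(res$selected_indices,
                   res$weights_used$ranking[seq_len(res$best_size)])
  # the decided subset is never worse than the full starting set
  expect_lte(min(res$rmse_curve$cv_rmse),
             res$rmse_curve$cv_rmse[res$rmse_curve$subset_size == 6])
  # and contains the true support here
  expect_true(all(c(1, 2) %in% res$selected_indices))
})

test_that("two-feature problems are handled down to singletons", {
  tab <- make_table(n = 60, p = 2, support = 1, effects = 3, noise = 0.2)
  cfg <- hofd_config(hybrid_mode = 1, start_size = 2, min_size = 1, seed = 2)
  res <- hofd_select(tab$X, tab$y, cfg)
  expect_setequal(res$rmse_curve$subset_size, c(2, 1))
  expect_true(res$best_size %in% c(1, 2))
  expect_error(hofd_select(tab$X[, 1, drop = FALSE], tab$y, cfg),
               class = "invalid_input")
})

test_that("decided feature names are invariant to column permutation", {
  tab <- make_table(n = 120, p = 5, support = c(1, 2), effects = c(3, 2),
                    noise = 0.3, seed = 13)
  colnames(tab$X) <- paste0("F", 1:5)
  cfg <- hofd_config(hybrid_mode = 1, start_size = 5, seed = 8)
  res1 <- hofd_select(tab$X, tab$y, cfg)
  perm <- c(4, 2, 5, 1, 3)
  res2 <- hofd_select(tab$X[, perm], tab$y, cfg)
  expect_setequal(res1$selected_names, res2$selected_names)
})

test_that("config validation rejects nonsense", {
  expect_error(hofd_config(hybrid_mode = 7), class = "invalid_config")
  expect_error(hofd_config(target = "MAP"), class = "invalid_config")
  expect_error(hofd_config(start_size = 2, min_size = 2),
               class = "invalid_config")
})

test_that("run_pipeline is deterministic and beats the mean predictor", {
  g <- generate_feature_table(synth_feature_config(
    n_segments = 120, n_features = 6, support = c(1, 2),
    effect_sizes = c(8, 6), noise_sd = 2, seed = 17))
  tab <- g$table
  cfg <- hofd_config(hybrid_mode = 1, start_size = 6, seed = 21)
  r1 <- run_pipeline(tab, cfg)
  r2 <- run_pipeline(tab, cfg)
  expect_equal(r1$eval$RMSE, r2$eval$RMSE, tolerance = 1e-12)
  expect_identical(r1$hofd$selected_names, r2$hofd$selected_names)

  # held-out RMSE beats predicting the training mean
  expect_lt(r1$eval$RMSE, sd(tab$SBP))
  expect_gt(r1$eval$R2, 0.5)
})

test_that("SBP and DBP targets are selected independently", {
  g <- generate_feature_table(synth_feature_config(
    n_segments = 100, n_features = 5, support = c(1, 2),
    effect_sizes = c(6, 4), noise_sd = 1.5, seed = 19))
  tab <- g$table
  # a DBP column driven by different features
  set.seed(77)
  tab$DBP <- 3 * tab[[4]] + rnorm(100, 0, 1)
  rs <- run_pipeline(tab, hofd_config(hybrid_mode = 1, start_size = 5,
                                      seed = 3, target = "SBP"))
  rd <- run_pipeline(tab, hofd_config(hybrid_mode = 1, start_size = 5,
                                      seed = 3, target = "DBP"))
  expect_true("F4" %in% rd$hofd$selected_names)
  expect_true(all(c("F1", "F2") %in% rs$hofd$selected_names))
  expect_false(identical(rs$hofd$weights_used$ranking,
                         rd$hofd$weights_used$ranking))
})

test_that("repeat averaging produces a merged report", {
  g <- generate_feature_table(synth_feature_config(
    n_segments = 80, n_features = 4, support = 1, effect_sizes = 8,
    noise_sd = 2, seed = 23))
  res <- run_pipeline(g$table, hofd_config(hybrid_mode = 1, start_size = 4,
                                           seed = 5), repeats = 2)
  expect_length(res$per_repeat, 2)
  expect_equal(res$eval$RMSE,
               mean(vapply(res$per_repeat, function(r) r$RMSE, numeric(1))))
  expect_equal(res$eval$n_repeats, 2)
})
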