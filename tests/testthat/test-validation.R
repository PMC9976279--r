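# Nested cross-validation protocol and final refit.

test_that("a single resample with a singleton grid equals a direct hold-out", {
  fx <- fixture_noiseless()
  X <- fx$X[1:100, ]; y <- fx$y[1:100]
  grid <- list(list(n_trees = 100L, max_features = "all"))
  rep <- nested_cv(X, y, "rf", grid = grid, n_resamples = 1, inner_k = 3,
                   seed = 42)
  rs <- rep$resamples[[1]]
  expect_equal(rs$chosen, grid[[1]])  # singleton grid is a no-op
  # recompute the hold-out RMSE from the stored split and seed
  m <- fit_model(model_spec("rf", rs$chosen, seed = rs$seed),
                 X[rs$train_ids, ], y[match(rs$train_ids, rownames(X))])
  pred <- predict(m, X[rs$test_ids, ])
  rmse <- sqrt(mean((pred - y[match(rs$test_ids, rownames(X))])^2))
  expect_equal(rs$stats$rmse, rmse)
  expect_setequal(c(rs$train_ids, rs$test_ids), rownames(X))
  expect_length(intersect(rs$train_ids, rs$test_ids), 0)
})

test_that("the report aggregation matches an independent recomputation", {
  fx <- fixture_tight()
  X <- fx$X[1:120, ]; y <- fx$y[1:120]
  rep <- nested_cv(X, y, "rf",
                   grid = param_grid(n_trees = c(50L, 100L)),
                   n_resamples = 4, inner_k = 3, seed = 7)
  rmses <- vapply(rep$resamples, function(r) r$stats$rmse, numeric(1))
  expect_equal(rep$summary$mean[rep$summary$statistic == "rmse"],
               mean(rmses))
  expect_equal(rep$summary$sd[rep$summary$statistic == "rmse"],
               sd(rmses))
  r2s <- vapply(rep$resamples, function(r) r$stats$r2, numeric(1))
  expect_equal(rep$summary$mean[rep$summary$statistic == "r2"], mean(r2s))
})

test_that("the full report is reproducible for a fixed master seed", {
  fx <- fixture_noiseless()
  X <- fx$X[1:80, ]; y <- fx$y[1:80]
  g <- param_grid(n_trees = c(50L, 100L))
  r1 <- nested_cv(X, y, "rf", grid = g, n_resamples = 2, inner_k = 3,
                  seed = 13)
  r2 <- nested_cv(X, y, "rf", grid = g, n_resamples = 2, inner_k = 3,
                  seed = 13)
  expect_identical(r1$summary, r2$summary)
  expect_identical(lapply(r1$resamples, `[[`, "test_ids"),
                   lapply(r2$resamples, `[[`, "test_ids"))
})

test_that("protocol preconditions are enforced", {
  fx <- fixture_noiseless()
  X <- fx$X[1:20, ]; y <- fx$y[1:20]
  expect_error(nested_cv(X, y, "rf", grid = list(list()), n_resamples = 1,
                         inner_k = 19, seed = 1),
               "inner_k")
  expect_error(nested_cv(X, rep(1, 20), "rf", grid = list(list()),
                         n_resamples = 1, inner_k = 3, seed = 1),
               "constant")
})

test_that("modal parameter choice picks the most frequent grid point", {
  rep <- list(resamples = list(list(chosen_index = 2, chosen = list(a = 2)),
                               list(chosen_index = 1, chosen = list(a = 1)),
                               list(chosen_index = 2, chosen = list(a = 2))))
  class(rep) <- "validation_report"
  expect_equal(modal_params(rep), list(a = 2))
})

test_that("final refit with reported parameters is referentially transparent", {
  fx <- fixture_noiseless()
  X <- fx$X[1:60, ]; y <- fx$y[1:60]
  fs <- final_fit(X, y, "rf", best_params = list(n_trees = 100L), seed = 3)
  m <- fit_model(model_spec("rf", list(n_trees = 100L), seed = 3), X, y)
  expect_identical(predict_final(fs, X), predict(m, X))
  # memorizing forest recovers training data after the refit
  fs2 <- final_fit(X, y, "rf",
                   best_params = list(n_trees = 200L, bootstrap = FALSE,
                                      max_features = "all"),
                   seed = 3)
  expect_lt(max(abs(predict_final(fs2, X) - y)), 0.05)
  expect_match(fs2$provenance, "family=rf")
})

test_that("nn validation scales features inside the training portion only", {
  fx <- fixture_noiseless()
  X <- fx$X[1:80, ]; y <- fx$y[1:80]
  rep <- nested_cv(X, y, "nn",
                   grid = list(list(widths = c(16L, 8L, 4L), epochs = 20L)),
                   n_resamples = 1, inner_k = 2, seed = 5)
  expect_true(rep$protocol$scale)
  expect_true(is.finite(rep$resamples[[1]]$stats$rmse))
})
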