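# Regressors: Random Forest and the feed-forward network.

test_that("a forest of deep trees memorizes separable data", {
  X <- withr::with_seed(1, matrix(rnorm(50), 10, 5,
                                  dimnames = list(NULL, paste0("f", 1:5))))
  y <- withr::with_seed(2, rnorm(10))
  m <- fit_model(model_spec("rf", list(n_trees = 200, bootstrap = FALSE)),
                 X, y)
  expect_lt(max(abs(predict(m, X) - y)), 0.05)
})

test_that("a constant target yields constant predictions", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_model(model_spec("rf", list(n_trees = 50)), X, rep(-2.5, 20))
  Xnew <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(m, Xnew), rep(-2.5, 5))
})

test_that("fits are deterministic given the seed, for both families", {
  fx <- fixture_noiseless()
  idx <- 1:120
  X <- fx$X[idx, ]; y <- fx$y[idx]
  for (fam in c("rf", "nn")) {
    params <- if (fam == "nn") list(widths = c(16L, 8L, 4L), epochs = 30L)
              else list(n_trees = 100)
    m1 <- fit_model(model_spec(fam, params, seed = 11L), X, y)
    m2 <- fit_model(model_spec(fam, params, seed = 11L), X, y)
    expect_identical(predict(m1, X), predict(m2, X))
  }
})

test_that("the network recovers a linear ground truth on noiseless data", {
  fx <- fixture_noiseless(500, seed = 11)
  sp <- split_fixture(fx$lib, "random", test_frac = 0.3, seed = 2)
  tr <- match(sp$train$records$id, rownames(fx$X))
  te <- match(sp$test$records$id, rownames(fx$X))
  sc <- fit_scaler(fx$X[tr, ])
  nn <- fit_model(model_spec("nn", list(widths = c(64L, 32L, 16L),
                                        epochs = 150L), seed = 5L),
                  apply_scaler(sc, fx$X[tr, ]), fx$y[tr])
  pred <- predict(nn, apply_scaler(sc, fx$X[te, ]))
  r2 <- 1 - sum((pred - fx$y[te])^2) / sum((fx$y[te] - mean(fx$y[te]))^2)
  expect_gte(r2, 0.9)
})

test_that("prediction respects row order and duplication", {
  fx <- fixture_noiseless()
  X <- fx$X[1:30, ]
  m <- fit_model(model_spec("rf", list(n_trees = 100)), X, fx$y[1:30])
  p <- predict(m, X)
  perm <- withr::with_seed(3, sample(30))
  expect_equal(predict(m, X[perm, ]), p[perm])
  expect_equal(predict(m, X[c(1, 1), ]), p[c(1, 1)])
})

test_that("column mismatches fail naming the offending columns", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_model(model_spec("rf", list(n_trees = 20)), X, rnorm(10))
  expect_error(predict(m, matrix(0, 1, 1, dimnames = list(NULL, "a"))),
               "missing: b")
  X3 <- matrix(0, 1, 3, dimnames = list(NULL, c("a", "b", "zz")))
  expect_error(predict(m, X3), "extra: zz")
})

test_that("forest predictions stay within the training target range", {
  fx <- fixture_noiseless()
  m <- fit_model(model_spec("rf", list(n_trees = 100)), fx$X, fx$y)
  far <- fx$X * 5  # extreme extrapolation
  p <- predict(m, far)
  expect_true(all(p >= min(fx$y) & p <= max(fx$y)))
})

test_that("Gini importances are a normalized ranking with the right dominance", {
  X <- withr::with_seed(4, matrix(rnorm(600), 200, 3,
                                  dimnames = list(NULL, c("A", "B", "C"))))
  y <- 3 * X[, "A"] + withr::with_seed(5, rnorm(200, sd = 0.05))
  m <- fit_model(model_spec("rf", list(n_trees = 200)), X, y)
  gi <- gini_importances(m)
  expect_equal(sum(gi$importance), 1)
  expect_true(all(diff(gi$importance) <= 0))
  expect_equal(gi$descriptor[1], "A")
  # undefined for the network family
  Xs <- X[1:20, ]
  nn <- fit_model(model_spec("nn", list(widths = c(8L, 4L, 2L),
                                        epochs = 5L)), Xs, y[1:20])
  expect_error(gini_importances(nn), "rf family")
})

test_that("the lipophilicity-proxy count dominates on the default library", {
  fx <- fixture_tight()
  m <- fit_model(model_spec("rf", list(n_trees = 300), seed = 2L),
                 fx$X[, colnames(fx$lib$counts)], fx$y)
  gi <- gini_importances(m)
  expect_equal(gi$descriptor[1], "aliphatic_carbons")
})

test_that("model bundles round-trip through their text format", {
  fx <- fixture_noiseless()
  X <- fx$X[1:50, ]; y <- fx$y[1:50]
  nn <- fit_model(model_spec("nn", list(widths = c(8L, 4L, 2L),
                                        epochs = 10L), seed = 3L), X, y)
  path <- withr::local_tempfile(fileext = ".json")
  save_model_bundle(nn, path)
  nn2 <- load_model_bundle(path)
  expect_equal(predict(nn2, X), predict(nn, X), tolerance = 1e-12)
  # rf bundles store the seeded spec; refitting reproduces the forest
  rf <- fit_model(model_spec("rf", list(n_trees = 50), seed = 9L), X, y)
  save_model_bundle(rf, path)
  spec2 <- load_model_bundle(path)
  rf2 <- fit_model(spec2, X, y)
  expect_identical(predict(rf2, X), predict(rf, X))
})
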