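# The experimental design used throughout: 50 outer resamples, each a random
# 70%/30% train/test split; hyperparameters tuned on each training portion by
# 5-fold cross-validation minimizing mean RMSE; the winning grid point refit
# on the full training portion and scored on the held-out 30%. Statistics are
# reported as mean +- SD over the resamples. Feature scaling, when used, is
# fit inside each training portion only, so no test information leaks into
# the transform.

#' Expand a hyperparameter grid
#'
#' @param ... named vectors/lists of candidate values; the grid is their
#'   Cartesian product. A list-valued entry (e.g. candidate width triples)
#'   is treated element-wise.
#' @return list of parameter lists, in grid order (first argument varies
#'   fastest).
#' @export
param_grid <- function(...) {
  args <- list(...)
  stopifnot(length(args) > 0, !is.null(names(args)), all(nzchar(names(args))))
  idx <- do.call(expand.grid, lapply(args, seq_along))
  lapply(seq_len(nrow(idx)), function(r) {
    out <- list()
    for (nm in names(args)) out[[nm]] <- args[[nm]][[idx[r, nm]]]
    out
  })
}

#' Default hyperparameter grids
#'
#' @param family `"rf"` or `"nn"`.
#' @return list of parameter lists for [nested_cv()].
#' @export
default_grid <- function(family = c("rf", "nn")) {
  family <- match.arg(family)
  if (family == "rf") {
    param_grid(n_trees = c(100L, 500L),
               max_features = c("sqrt", "third", "all"),
               min_samples_leaf = c(1L, 3L))
  } else {
    param_grid(widths = list(c(256L, 128L, 64L), c(128L, 64L, 32L)),
               lr = c(1e-3, 1e-4))
  }
}

.rmse <- function(a, b) sqrt(mean((a - b)^2))

.fit_scaled <- function(family, params, seed, X, y, scale) {
  scaler <- NULL
  if (scale) {
    scaler <- fit_scaler(X)
    X <- apply_scaler(scaler, X)
  }
  model <- fit_model(model_spec(family, params = params, seed = seed), X, y)
  list(model = model, scaler = scaler)
}

.predict_scaled <- function(fs, X) {
  if (!is.null(fs$scaler)) X <- apply_scaler(fs$scaler, X)
  predict(fs$model, X)
}

#' Nested cross-validation of a model family
#'
#' For each of `n_resamples` outer resamples: draw a random
#' `1 - test_frac` / `test_frac` train/test split; score every grid point by
#' `inner_k`-fold cross-validation on the training portion (mean RMSE over
#' folds; folds are fixed per resample, shared by all grid points); refit the
#' best grid point (ties broken by grid order) on the whole training portion;
#' predict and score the test portion. Per-resample seeds are spawned
#' deterministically from `seed`, so the full report is reproducible.
#'
#' @param X numeric feature matrix with molecule ids as row names.
#' @param y numeric response, log10 molar log(S), aligned with `X` rows.
#' @param family `"rf"` or `"nn"`.
#' @param grid list of candidate parameter lists (see [param_grid()]); a
#'   single-point grid makes tuning a no-op.
#' @param n_resamples number of outer resamples.
#' @param test_frac outer test fraction.
#' @param inner_k folds of the inner tuning loop.
#' @param seed master seed.
#' @param scale fit a [fit_scaler()] inside every training portion (default:
#'   only for the nn family).
#' @return object of class `validation_report`: per-resample results
#'   (indices, chosen parameters, test-set `eval_stats`) and a `summary`
#'   data.frame of mean and SD per statistic.
#' @export
nested_cv <- function(X, y, family = c("rf", "nn"), grid = default_grid(family),
                      n_resamples = 50L, test_frac = 0.30, inner_k = 5L,
                      seed = 1L, scale = (family == "nn")) {
  family <- match.arg(family)
  stopifnot(is.matrix(X), nrow(X) == length(y), length(grid) >= 1,
            test_frac > 0, test_frac < 1, inner_k >= 2, n_resamples >= 1)
  n <- nrow(X)
  n_test <- floor(n * test_frac)
  n_train <- n - n_test
  if (inner_k > n_train)
    stop("nested_cv: inner_k (", inner_k, ") exceeds the training size (",
         n_train, ")")
  if (stats::var(y) == 0) stop("nested_cv: degenerate constant response")
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  resample_seeds <- with_local_seed(seed,
                                    sample.int(2147483646L, n_resamples))
  resamples <- vector("list", n_resamples)
  for (r in seq_len(n_resamples)) {
    rs <- resample_seeds[r]
    sel <- with_local_seed(rs, {
      test_idx <- sort(sample.int(n, n_test))
      folds <- sample(rep_len(seq_len(inner_k), n_train))
      list(test_idx = test_idx, folds = folds)
    })
    train_idx <- setdiff(seq_len(n), sel$test_idx)
    Xtr <- X[train_idx, , drop = FALSE]; ytr <- y[train_idx]

    inner_rmse <- vapply(grid, function(params) {
      fold_rmse <- vapply(seq_len(inner_k), function(k) {
        hold <- sel$folds == k
        fs <- .fit_scaled(family, params, rs, Xtr[!hold, , drop = FALSE],
                          ytr[!hold], scale)
        .rmse(.predict_scaled(fs, Xtr[hold, , drop = FALSE]), ytr[hold])
      }, numeric(1))
      mean(fold_rmse)
    }, numeric(1))
    best <- which.min(inner_rmse)  # ties: first in grid order

    fs <- .fit_scaled(family, grid[[best]], rs, Xtr, ytr, scale)
    pred <- .predict_scaled(fs, X[sel$test_idx, , drop = FALSE])
    stats_r <- evaluate(prediction_set(ids[sel$test_idx], pred,
                                       y[sel$test_idx]))
    resamples[[r]] <- list(index = r, seed = rs,
                           train_ids = ids[train_idx],
                           test_ids = ids[sel$test_idx],
                           chosen = grid[[best]],
                           chosen_index = best,
                           inner_rmse = inner_rmse,
                           stats = stats_r)
  }
  structure(list(
    resamples = resamples,
    summary = summarize_resamples(resamples),
    protocol = list(family = family, n_resamples = n_resamples,
                    test_frac = test_frac, inner_k = inner_k, seed = seed,
                    scale = scale, grid_size = length(grid))
  ), class = "validation_report")
}

#' Aggregate per-resample statistics into mean and SD
#'
#' @param resamples list of per-resample results (each with an `eval_stats`
#'   in `$stats`), e.g. `report$resamples`.
#' @return data.frame with one row per statistic and columns `mean`, `sd`.
#' @export
summarize_resamples <- function(resamples) {
  fields <- c("r2", "rmse", "bias", "sdep", "pct_within_half")
  vals <- sapply(fields, function(f)
    vapply(resamples, function(r) r$stats[[f]], numeric(1)))
  vals <- matrix(vals, nrow = length(resamples),
                 dimnames = list(NULL, fields))
  data.frame(statistic = fields,
             mean = colMeans(vals),
             sd = apply(vals, 2, stats::sd),
             row.names = NULL)
}

#' @export
print.validation_report <- function(x, ...) {
  p <- x$protocol
  cat("<validation_report> ", p$family, ", ", p$n_resamples, " resamples (",
      round(100 * (1 - p$test_frac)), "%/", round(100 * p$test_frac),
      "% splits), inner ", p$inner_k, "-fold, grid of ", p$grid_size,
      "\n", sep = "")
  s <- x$summary
  for (r in seq_len(nrow(s)))
    cat(sprintf("  %-16s %7.3f +- %.3f\n", s$statistic[r], s$mean[r], s$sd[r]))
  invisible(x)
}

#' Most frequently selected hyperparameters across resamples
#'
#' The modal grid point; ties broken by grid order.
#'
#' @param report a `validation_report`.
#' @return parameter list.
#' @export
modal_params <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  picks <- vapply(report$resamples, `[[`, numeric(1), "chosen_index")
  tab <- tabulate(picks)
  report$resamples[[which(picks == which.max(tab))[1]]]$chosen
}

#' Refit the chosen model on all data
#'
#' After validation, the selected hyperparameters are used to retrain on
#' 100% of the data before predicting external test sets.
#'
#' @param X,y full feature matrix and response.
#' @param family `"rf"` or `"nn"`.
#' @param best_params parameter list, typically [modal_params()] of a report.
#' @param seed integer seed.
#' @param scale as in [nested_cv()].
#' @return list with the fitted `model`, the `scaler` (or `NULL`), and a
#'   `provenance` string recording the parameters and seed.
#' @export
final_fit <- function(X, y, family = c("rf", "nn"), best_params,
                      seed = 1L, scale = (family == "nn")) {
  family <- match.arg(family)
  fs <- .fit_scaled(family, best_params, seed, X, y, scale)
  fs$provenance <- paste0(
    "family=", family, "; seed=", seed, "; params={",
    paste(names(best_params),
          vapply(best_params, function(p) paste(p, collapse = "x"),
                 character(1)),
          sep = "=", collapse = ", "), "}; n=", nrow(X))
  fs
}

#' Predict with a final_fit result
#' @param fs result of [final_fit()].
#' @param X feature matrix.
#' @return numeric predictions.
#' @export
predict_final <- function(fs, X) .predict_scaled(fs, X)
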