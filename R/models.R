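# Descriptor-based regressors: Random Forest (via ranger) and the
# fixed-shape feed-forward network (see mlp.R), behind one fit/predict
# surface, plus Gini-importance extraction for the forests.

#' Specify a regression model
#'
#' @param family `"rf"` (Random Forest) or `"nn"` (3-hidden-layer ReLU/Adam
#'   feed-forward network).
#' @param params named list of hyperparameters. For `rf`: `n_trees`,
#'   `max_depth` (0 = unlimited), `min_samples_leaf`, `max_features` (one of
#'   `"sqrt"`, `"third"`, `"all"`, or a count). For `nn`: `widths` (three
#'   strictly decreasing hidden-layer sizes), `lr`, `batch_size`, `epochs`.
#' @param seed integer seed; fits are deterministic given the seed.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("rf", "nn"), params = list(), seed = 1L) {
  family <- match.arg(family)
  defaults <- if (family == "rf") {
    list(n_trees = 500L, max_depth = 0L, min_samples_leaf = 1L,
         max_features = "third", bootstrap = TRUE)
  } else {
    list(widths = c(128L, 64L, 32L), lr = 1e-3, batch_size = 32L,
         epochs = 200L)
  }
  params <- utils::modifyList(defaults, params)
  if (family == "nn") {
    stopifnot(length(params$widths) == 3, all(diff(params$widths) < 0),
              all(params$widths > 0), params$lr > 0, params$epochs >= 1,
              params$batch_size >= 1)
  } else {
    stopifnot(params$n_trees >= 1, params$min_samples_leaf >= 1)
  }
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "model_spec")
}

.mtry_from <- function(max_features, d) {
  if (is.numeric(max_features)) return(max(1L, min(d, as.integer(max_features))))
  switch(max_features,
         sqrt = max(1L, floor(sqrt(d))),
         third = max(1L, floor(d / 3)),
         all = d,
         stop("unknown max_features: ", max_features))
}

#' Fit a regression model
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix with column names.
#' @param y numeric response vector, log10 molar log(S).
#' @return object of class `solq_model`.
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"), is.matrix(X),
            nrow(X) == length(y), nrow(X) >= 2, !is.null(colnames(X)))
  if (any(!is.finite(y))) stop("fit_model: non-finite response values")
  p <- spec$params
  fit <- if (spec$family == "rf") {
    ranger::ranger(
      y = y, x = as.data.frame(X),
      num.trees = p$n_trees,
      mtry = .mtry_from(p$max_features, ncol(X)),
      min.node.size = p$min_samples_leaf,
      max.depth = p$max_depth,
      replace = isTRUE(p$bootstrap),
      sample.fraction = 1,
      importance = "impurity",
      seed = spec$seed,
      num.threads = 1
    )
  } else {
    mlp_fit(X, y, widths = p$widths, lr = p$lr, epochs = p$epochs,
            batch_size = p$batch_size, seed = spec$seed)
  }
  structure(list(spec = spec, fit = fit, columns = colnames(X),
                 y_range = range(y)),
            class = "solq_model")
}

#' @export
print.solq_model <- function(x, ...) {
  cat("<solq_model> family ", x$spec$family, ", ", length(x$columns),
      " descriptors, seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Predict log(S) for new molecules
#'
#' @param object a fitted `solq_model`.
#' @param X feature matrix whose columns must match the training columns.
#' @param ... unused.
#' @return numeric vector of predicted log10 molar log(S).
#' @export
predict.solq_model <- function(object, X, ...) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  missing_cols <- setdiff(object$columns, colnames(X))
  extra_cols <- setdiff(colnames(X), object$columns)
  if (length(missing_cols) || length(extra_cols))
    stop("predict: column mismatch (missing: ",
         paste(missing_cols, collapse = ", "), "; extra: ",
         paste(extra_cols, collapse = ", "), ")")
  X <- X[, object$columns, drop = FALSE]
  out <- if (object$spec$family == "rf") {
    predict(object$fit, data = as.data.frame(X),
            num.threads = 1)$predictions
  } else {
    mlp_predict(object$fit, X)
  }
  stopifnot(all(is.finite(out)))
  as.numeric(out)
}

#' Gini (impurity) feature importances of a Random Forest
#'
#' Total impurity decrease attributable to each descriptor, normalized to
#' sum to one and sorted in decreasing order. Undefined for the neural
#' network family.
#'
#' @param model a fitted `solq_model` of family `"rf"`.
#' @return data.frame with columns `descriptor`, `importance`.
#' @export
gini_importances <- function(model) {
  stopifnot(inherits(model, "solq_model"))
  if (model$spec$family != "rf")
    stop("gini_importances: only defined for the rf family")
  imp <- model$fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  imp <- sort(imp, decreasing = TRUE)
  data.frame(descriptor = names(imp), importance = as.numeric(imp),
             row.names = NULL)
}

#' Save / load a fitted model bundle
#'
#' The bundle is a versioned plain-text JSON file: model family, seed,
#' hyperparameters, training columns, and the learned state (forest: not
#' serializable as text, so rf bundles store the spec and must be refit from
#' data; nn: full weight matrices). A stored rf bundle plus the original
#' training data reproduces the identical forest because fits are seeded.
#'
#' @param model a `solq_model`.
#' @param path file path.
#' @name model_bundle
#' @export
save_model_bundle <- function(model, path) {
  stopifnot(inherits(model, "solq_model"))
  bundle <- list(
    format = "solqspr-model",
    version = 1L,
    family = model$spec$family,
    seed = model$spec$seed,
    params = model$spec$params,
    columns = model$columns,
    y_range = model$y_range
  )
  if (model$spec$family == "nn") {
    bundle$weights <- lapply(model$fit$par$W, function(w)
      list(dim = dim(w), values = as.numeric(w)))
    bundle$biases <- model$fit$par$b
    bundle$widths <- model$fit$widths
  }
  writeLines(jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @param path file path.
#' @rdname model_bundle
#' @return `load_model_bundle()` returns a `solq_model` for nn bundles and a
#'   `model_spec` (to be refit) for rf bundles.
#' @export
load_model_bundle <- function(path) {
  bundle <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stopifnot(identical(bundle$format, "solqspr-model"))
  params <- lapply(bundle$params, function(p)
    if (is.list(p)) unlist(p) else p)
  if (bundle$family == "nn") params$widths <- as.integer(params$widths)
  spec <- model_spec(bundle$family, params = params, seed = bundle$seed)
  if (bundle$family == "rf") return(spec)
  W <- vector("list", length(bundle$biases))
  b <- vector("list", length(bundle$biases))
  for (l in seq_along(W)) {
    d <- unlist(bundle$weights[[l]]$dim)
    W[[l]] <- matrix(unlist(bundle$weights[[l]]$values), d[1], d[2])
    b[[l]] <- unlist(bundle$biases[[l]])
  }
  fit <- list(par = list(W = W, b = b), val_mse = NA_real_,
              widths = as.integer(unlist(bundle$widths)))
  structure(list(spec = spec, fit = fit,
                 columns = unlist(bundle$columns),
                 y_range = as.numeric(unlist(bundle$y_range))),
            class = "solq_model")
}
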