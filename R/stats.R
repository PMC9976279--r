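# Prediction-set statistics: R^2, RMSE, and the decomposition of RMSE into
# bias (mean displacement, the systematic error) and SDEP (standard deviation
# of the error of prediction, the random error), with RMSE^2 = SDEP^2 +
# bias^2 holding exactly because SDEP uses the population (divide-by-N) form.
# Errors are calculated as (calculated - experimental), so a positive bias
# means solubility is overpredicted.

#' Construct a prediction set
#'
#' @param ids molecule ids.
#' @param y_calc calculated log10 molar log(S) values.
#' @param y_exp experimental log10 molar log(S) values.
#' @return object of class `prediction_set`.
#' @export
prediction_set <- function(ids, y_calc, y_exp) {
  stopifnot(length(ids) == length(y_calc), length(y_calc) == length(y_exp),
            length(y_exp) >= 1, all(is.finite(y_calc)), all(is.finite(y_exp)))
  structure(list(ids = as.character(ids), y_calc = as.numeric(y_calc),
                 y_exp = as.numeric(y_exp), n = length(y_exp)),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set> ", x$n, " molecules\n", sep = "")
  invisible(x)
}

#' Evaluate a prediction set
#'
#' Computes the coefficient of determination about the experimental mean
#' (which may be negative when predictions are worse than the null model),
#' RMSE, bias = mean(y_calc - y_exp), SDEP = population SD of the error, and
#' the percentage of predictions within +-0.5 log units (inclusive). The
#' identity RMSE^2 = SDEP^2 + bias^2 is asserted on construction.
#'
#' @param p a [prediction_set()].
#' @return object of class `eval_stats` with fields `r2`, `rmse`, `bias`,
#'   `sdep`, `pct_within_half`, `n`. `r2` is `NA` when the experimental
#'   values have zero variance.
#' @export
evaluate <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  err <- p$y_calc - p$y_exp
  rmse <- sqrt(mean(err^2))
  bias <- mean(err)
  sdep <- sqrt(mean((err - bias)^2))
  ss_tot <- sum((p$y_exp - mean(p$y_exp))^2)
  r2 <- if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_
  eval_stats(r2 = r2, rmse = rmse, bias = bias, sdep = sdep,
             pct_within_half = 100 * mean(abs(err) <= 0.5), n = p$n)
}

#' Bundle evaluation statistics, asserting the error decomposition
#'
#' @param r2,rmse,bias,sdep,pct_within_half,n statistic values.
#' @return object of class `eval_stats`.
#' @export
eval_stats <- function(r2, rmse, bias, sdep, pct_within_half, n) {
  stopifnot(sdep >= 0, rmse >= 0,
            pct_within_half >= 0, pct_within_half <= 100,
            abs(rmse^2 - (sdep^2 + bias^2)) < 1e-9)
  structure(list(r2 = r2, rmse = rmse, bias = bias, sdep = sdep,
                 pct_within_half = pct_within_half, n = as.integer(n)),
            class = "eval_stats")
}

#' @export
print.eval_stats <- function(x, ...) {
  cat(sprintf(
    "<eval_stats> n = %d: R2 = %s, RMSE = %.3f, SDEP = %.3f, bias = %+.3f, %%+-0.5 log = %.0f\n",
    x$n, ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2)), x$rmse, x$sdep,
    x$bias, x$pct_within_half))
  invisible(x)
}

#' @export
as.data.frame.eval_stats <- function(x, ...) {
  data.frame(R2 = x$r2, RMSE = x$rmse, SDEP = x$sdep, bias = x$bias,
             pct_within_half = x$pct_within_half, n = x$n)
}

#' Recompose RMSE from its SDEP and bias components
#'
#' The exact identity RMSE = sqrt(SDEP^2 + bias^2), used to cross-check
#' published statistics tables from their printed components.
#'
#' @param sdep standard deviation of the error of prediction (>= 0).
#' @param bias mean displacement.
#' @return RMSE.
#' @export
rmse_from_components <- function(sdep, bias) {
  stopifnot(all(sdep >= 0))
  sqrt(sdep^2 + bias^2)
}

#' Does a model predict worse than the null model?
#'
#' A model whose RMSE exceeds the standard deviation of the experimental
#' data is less accurate than simply predicting the experimental mean. The
#' comparison is strict: `rmse == exp_sd` is not flagged.
#'
#' @param stats an `eval_stats` object, or a bare RMSE value.
#' @param exp_sd standard deviation of the experimental values (>= 0).
#' @return `TRUE` when the model is worse than the null model.
#' @export
null_model_flag <- function(stats, exp_sd) {
  stopifnot(exp_sd >= 0)
  rmse <- if (inherits(stats, "eval_stats")) stats$rmse else stats
  rmse > exp_sd
}

#' Restrict a prediction set to an experimental solubility range
#'
#' Retains molecules with `lower < y_exp < upper` (strict bounds). The
#' defaults are the experimental range of the low-variance challenge test
#' set, used to score the high-variance set on a comparable range.
#'
#' @param p a [prediction_set()].
#' @param lower,upper strict range bounds (log10 molar).
#' @return a `prediction_set`; may be empty (flagged with attribute
#'   `empty = TRUE`).
#' @export
range_restrict <- function(p, lower = -6.79, upper = -1.18) {
  stopifnot(inherits(p, "prediction_set"), lower < upper)
  keep <- p$y_exp > lower & p$y_exp < upper
  if (!any(keep)) {
    out <- structure(list(ids = character(0), y_calc = numeric(0),
                          y_exp = numeric(0), n = 0L),
                     class = "prediction_set")
    attr(out, "empty") <- TRUE
    return(out)
  }
  prediction_set(p$ids[keep], p$y_calc[keep], p$y_exp[keep])
}

#' Write evaluation statistics as a CSV row block
#'
#' Column order follows the conventional reporting layout (R2, RMSE, SDEP,
#' bias, % within +-0.5 log).
#'
#' @param stats named list of `eval_stats` (names become the `model` column).
#' @param path output CSV path.
#' @export
write_stats_csv <- function(stats, path) {
  stopifnot(is.list(stats), !is.null(names(stats)))
  rows <- do.call(rbind, lapply(stats, as.data.frame))
  rows <- cbind(model = names(stats), rows)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
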