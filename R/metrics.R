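#' Regression metrics
#'
#' Standard definitions: \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, maximum absolute
#' error, mean absolute error and mean squared error. With zero variance in
#' the truths R2 is undefined and reported `NA` with a flag.
#'
#' @param predictions,truths equal-length numeric vectors (n >= 2)
#' @return a `metrics_record` list: `r2`, `maxae`, `mae`, `mse`,
#'   `r2_undefined`
#' @examples
#' evaluate_predictions(c(0.1, 0.9), c(0, 1))
#' @export
evaluate_predictions <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length")
  if (length(truths) < 2) stop("need at least 2 points")
  err <- truths - predictions
  ss_tot <- sum((truths - mean(truths))^2)
  structure(list(
    r2 = if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_,
    maxae = max(abs(err)), mae = mean(abs(err)), mse = mean(err^2),
    r2_undefined = ss_tot <= 0),
    class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("R2 %.4f | MaxAE %.4f | MAE %.4f | MSE %.5f\n",
              x$r2, x$maxae, x$mae, x$mse))
  invisible(x)
}

#' Leave-one-out cross-validated Q2
#'
#' For every row the model is refit on the remaining rows (normalization
#' statistics refit inside each fold, so the left-out point never leaks into
#' the scaling) and the left-out value predicted;
#' \eqn{Q^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2}. When the spec
#' carries no fixed hyperparameters they are tuned once on the full set and
#' then held fixed across folds (tuning inside every fold of a
#' leave-one-out loop is not affordable for the tree families and does not
#' change the stability reading).
#'
#' @param spec a [model_spec()] or a `trained_model` whose tuned
#'   hyperparameters are reused
#' @param rows data frame with descriptors and target (n >= 3)
#' @param target target column name
#' @param descriptors descriptor columns (default: as in
#'   [train_single_model()])
#' @return list `q2`, `predictions` (the LOO predictions in row order)
#' @export
loo_q2 <- function(spec, rows, target = "phi_delta", descriptors = NULL) {
  if (inherits(spec, "trained_model")) {
    if (is.null(descriptors)) descriptors <- spec$descriptors
    spec <- frozen_spec(spec)
  }
  stopifnot(inherits(spec, "model_spec"))
  rows <- as.data.frame(rows, check.names = FALSE)
  n <- nrow(rows)
  if (n < 3) stop("leave-one-out needs at least 3 rows")
  if (is.null(spec$params)) {
    tuned <- train_single_model(spec, rows, target = target,
                                descriptors = descriptors)
    spec <- frozen_spec(tuned)
    if (is.null(descriptors)) descriptors <- tuned$descriptors
  }
  preds <- vapply(seq_len(n), function(i) {
    m <- train_single_model(spec, rows[-i, , drop = FALSE], target = target,
                            descriptors = descriptors)
    predict(m, rows[i, , drop = FALSE])
  }, numeric(1))
  y <- rows[[target]]
  list(q2 = 1 - sum((y - preds)^2) / sum((y - mean(y))^2),
       predictions = preds)
}

#' QSPR acceptability gate
#'
#' A model is an acceptable QSPR model when its internal cross-validated Q2
#' and its external-test R2 both reach the conventional 0.6 thresholds.
#'
#' @param q2 internal (e.g. leave-one-out) Q2
#' @param r2_external R2 on the external test set
#' @param q2_threshold,r2_threshold acceptance thresholds
#' @return list `pass` (logical) and `reasons` (character, empty on pass)
#' @examples
#' qspr_gate(0.62, 0.81)        # pass
#' qspr_gate(0.59, 0.81)$reasons
#' @export
qspr_gate <- function(q2, r2_external, q2_threshold = 0.6,
                      r2_threshold = 0.6) {
  if (is.na(q2) || is.na(r2_external))
    stop("both Q2 and external R2 must be present")
  reasons <- character(0)
  if (q2 < q2_threshold)
    reasons <- c(reasons, sprintf("Q2 = %.3f < %.2f", q2, q2_threshold))
  if (r2_external < r2_threshold)
    reasons <- c(reasons, sprintf("external R2 = %.3f < %.2f",
                                  r2_external, r2_threshold))
  list(pass = length(reasons) == 0, reasons = reasons)
}
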