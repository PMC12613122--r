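#' Shapley-value descriptor importance ranking
#'
#' Ranks the descriptors of a trained model by mean absolute Shapley
#' attribution over a set of rows. Tree models (XGBoost) use the exact
#' tree-path attribution built into the booster; every other family uses a
#' permutation-sampling Shapley estimator: for each sampled feature
#' ordering, features are switched one by one from a background row to the
#' explained row and the change in model output is credited to the switched
#' feature. The estimator is deterministic under a fixed seed.
#'
#' @param model a `trained_model`
#' @param rows data frame of rows to explain (typically the training set)
#' @param nperm number of sampled permutations per row (sampling backend)
#' @param background optional background rows (default: `rows`)
#' @param seed integer seed
#' @return data frame `descriptor`, `importance` (mean |attribution|),
#'   sorted decreasing, with attribute `backend`
#' @export
shap_rank <- function(model, rows, nperm = 30, background = NULL, seed = 1) {
  stopifnot(inherits(model, "trained_model"))
  rows <- as.data.frame(rows, check.names = FALSE)
  X <- if (is.null(model$normalizer)) rows[model$descriptors]
       else apply_normalizer(model$normalizer, rows)
  X <- as.matrix(X[model$descriptors])
  p <- ncol(X); n <- nrow(X)

  if (model$family == "xgb") {
    contrib <- stats::predict(model$fit$fit, X, type = "contrib")
    contrib <- contrib[, seq_len(p), drop = FALSE]  # drop the intercept column
    imp <- colMeans(abs(contrib))
    backend <- "tree-exact"
  } else {
    B <- if (is.null(background)) X else {
      bg <- if (is.null(model$normalizer)) background[model$descriptors]
            else apply_normalizer(model$normalizer, background)
      as.matrix(bg[model$descriptors])
    }
    phi <- with_local_seed(seed, {
      acc <- matrix(0, n, p)
      for (r in seq_len(nperm)) {
        ordp <- sample.int(p)
        bg_rows <- B[sample.int(nrow(B), n, replace = TRUE), , drop = FALSE]
        cur <- bg_rows
        prev_pred <- predict_family(model$fit, cur)
        for (j in ordp) {
          cur[, j] <- X[, j]
          pred <- predict_family(model$fit, cur)
          acc[, j] <- acc[, j] + (pred - prev_pred)
          prev_pred <- pred
        }
      }
      acc / nperm
    })
    imp <- colMeans(abs(phi))
    backend <- "permutation-sampling"
  }
  out <- data.frame(descriptor = model$descriptors, importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "backend") <- backend
  out
}
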