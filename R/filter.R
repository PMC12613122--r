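#' SHAP-guided descriptor filtering
#'
#' The small-data protocol: train the model on the full descriptor set, rank
#' descriptors by Shapley importance, then retrain on the top-k subsets for
#' k in `sizes` (default 30 to 50 in steps of 5). Each subset model is
#' reported with training R2, test R2 and leave-one-out Q2, mirroring the
#' descriptor-filter tables of the protocol; the returned best model is the
#' one with the highest LOO Q2 (ties break toward fewer descriptors;
#' `select_by` switches the criterion). Sizes exceeding the descriptor count
#' are capped (and the cap logged in the report).
#'
#' @param spec a [model_spec()]
#' @param train,test feature tables (train rows drive ranking, retraining
#'   and LOO; test rows only score the subset models)
#' @param sizes candidate descriptor-set sizes
#' @param target target column
#' @param descriptors full descriptor set (default: all numeric descriptor
#'   columns)
#' @param select_by `"loo_q2"` (default), `"test_r2"` or `"train_r2"`
#' @param nperm permutations for the sampling Shapley backend
#' @return list `best_model`, `best_size`, `ranking`, `report` (one row per
#'   evaluated size), `full_model`
#' @export
descriptor_filter <- function(spec, train, test,
                              sizes = c(30, 35, 40, 45, 50),
                              target = "phi_delta", descriptors = NULL,
                              select_by = c("loo_q2", "test_r2", "train_r2"),
                              nperm = 30) {
  select_by <- match.arg(select_by)
  full <- train_single_model(spec, train, target = target,
                             descriptors = descriptors)
  ranking <- shap_rank(full, train, nperm = nperm, seed = spec$seed)
  p <- nrow(ranking)
  eval_sizes <- unique(as.integer(pmin(sizes, p)))
  capped <- any(sizes > p)
  if (capped)
    message(sprintf("descriptor count %d caps requested sizes to {%s}",
                    p, paste(eval_sizes, collapse = ", ")))
  report <- data.frame()
  models <- list()
  for (k in eval_sizes) {
    keep <- ranking$descriptor[seq_len(k)]
    m <- train_single_model(spec, train, target = target, descriptors = keep)
    tr <- evaluate_predictions(predict(m, train), train[[target]])
    te <- evaluate_predictions(predict(m, test), test[[target]])
    q2 <- loo_q2(m, train, target = target)$q2
    models[[as.character(k)]] <- m
    report <- rbind(report, data.frame(
      size = k, train_r2 = tr$r2, test_r2 = te$r2, loo_q2 = q2,
      test_mae = te$mae, capped = capped && k == p))
  }
  crit <- switch(select_by, loo_q2 = report$loo_q2,
                 test_r2 = report$test_r2, train_r2 = report$train_r2)
  # ties break toward the smaller size (report rows are size-ascending)
  best_row <- which(crit == max(crit))[1]
  list(best_model = models[[as.character(report$size[best_row])]],
       best_size = report$size[best_row],
       ranking = ranking, report = report, full_model = full)
}
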