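#' Delta-learning residual stack
#'
#' Fits a base model on the target, then one or more delta models, each on
#' the training residuals left by the previous stage; the final prediction
#' is the base prediction plus all delta corrections. The default pairing
#' (SVR base, KRR delta, two layers) mirrors the bilayer configuration of
#' the modeling protocol; arbitrary depth is supported.
#'
#' @param base_spec [model_spec()] of the base layer
#' @param delta_specs list of specs for the delta layers (recycled when
#'   `layers` exceeds its length)
#' @param rows training data frame
#' @param target target column
#' @param descriptors shared descriptor manifest for every layer
#' @param layers total number of layers (>= 2)
#' @return a `delta_learning_model`
#' @export
fit_dlm <- function(base_spec = model_spec("svr"),
                    delta_specs = list(model_spec("krr")),
                    rows, target = "phi_delta", descriptors = NULL,
                    layers = 2) {
  if (layers < 2) stop("a delta-learning model needs at least 2 layers")
  rows <- as.data.frame(rows, check.names = FALSE)
  base <- train_single_model(base_spec, rows, target = target,
                             descriptors = descriptors)
  models <- list(base)
  resid <- rows[[target]] - predict(base, rows)
  for (l in seq_len(layers - 1)) {
    spec <- delta_specs[[((l - 1) %% length(delta_specs)) + 1]]
    drows <- rows
    drows[[".dlm_resid"]] <- resid
    m <- train_single_model(spec, drows, target = ".dlm_resid",
                            descriptors = base$descriptors)
    models[[length(models) + 1]] <- m
    resid <- resid - predict(m, rows)
  }
  structure(list(models = models, descriptors = base$descriptors,
                 target = target),
            class = "delta_learning_model")
}

#' Predict from a delta-learning model
#' @param object a `delta_learning_model`
#' @param newdata data frame with the shared descriptor manifest
#' @param ... unused
#' @return numeric predictions (base plus all delta corrections)
#' @export
predict.delta_learning_model <- function(object, newdata, ...) {
  missing <- setdiff(object$descriptors, names(newdata))
  if (length(missing) > 0)
    stop(sprintf("newdata is missing descriptor column(s): %s",
                 paste(missing, collapse = ", ")))
  Reduce(`+`, lapply(object$models, function(m) predict(m, newdata)))
}

#' Mixture-of-experts ensemble
#'
#' Fits each expert independently on the training rows, then chooses a
#' global convex weight vector over the experts by seeded search on the
#' probability simplex. Weights are scored against out-of-fold
#' cross-validated expert predictions by default (scoring against raw
#' training fits is available but lets an overfitting expert absorb all the
#' weight); the candidate pool always contains every unit-weight vector, so
#' the fitted-set loss of the mixture never exceeds the best single
#' expert's.
#'
#' @param expert_specs list of >= 2 [model_spec()]s
#' @param rows training data frame
#' @param target target column
#' @param descriptors shared descriptor manifest
#' @param budget number of candidate weight vectors (>= number of experts
#'   + 1, to cover the unit vectors and at least one mixture)
#' @param seed integer seed
#' @param weight_on `"oof"` (default) or `"fit"`
#' @param folds folds for the out-of-fold predictions
#' @return a `mixture_of_experts`
#' @export
fit_moe <- function(expert_specs, rows, target = "phi_delta",
                    descriptors = NULL, budget = 100, seed = 1,
                    weight_on = c("oof", "fit"), folds = 5) {
  if (length(expert_specs) < 2) stop("need at least 2 experts")
  if (budget < length(expert_specs) + 1)
    stop("weight budget must be at least the number of experts + 1")
  weight_on <- match.arg(weight_on)
  rows <- as.data.frame(rows, check.names = FALSE)
  n <- nrow(rows); ne <- length(expert_specs)
  experts <- lapply(expert_specs, train_single_model, rows = rows,
                    target = target, descriptors = descriptors)
  y <- rows[[target]]
  scoring <- with_local_seed(seed + 1L, {
    if (weight_on == "fit") {
      sapply(experts, function(m) predict(m, rows))
    } else {
      fl <- cv_folds(n, folds)
      P <- matrix(NA_real_, n, ne)
      for (k in seq_along(expert_specs)) {
        fx <- frozen_spec(experts[[k]])
        for (f in fl) {
          m <- train_single_model(fx, rows[-f, , drop = FALSE],
                                  target = target,
                                  descriptors = experts[[k]]$descriptors)
          P[f, k] <- predict(m, rows[f, , drop = FALSE])
        }
      }
      P
    }
  })
  cand <- with_local_seed(seed, {
    unit <- diag(ne)
    extra <- matrix(stats::rexp(max(0, budget - ne) * ne),
                    ncol = ne)
    extra <- extra / rowSums(extra)
    rbind(unit, extra)
  })
  loss <- apply(cand, 1, function(w) mean((y - scoring %*% w)^2))
  w <- cand[which.min(loss), ]
  structure(list(experts = experts, weights = w,
                 descriptors = experts[[1]]$descriptors,
                 weight_on = weight_on, fitted_loss = min(loss)),
            class = "mixture_of_experts")
}

#' Predict from a mixture-of-experts model
#' @param object a `mixture_of_experts`
#' @param newdata data frame with the shared descriptor manifest
#' @param ... unused
#' @return numeric predictions, the weight-averaged expert outputs
#' @export
predict.mixture_of_experts <- function(object, newdata, ...) {
  missing <- setdiff(object$descriptors, names(newdata))
  if (length(missing) > 0)
    stop(sprintf("newdata is missing descriptor column(s): %s",
                 paste(missing, collapse = ", ")))
  P <- sapply(object$experts, function(m) predict(m, newdata))
  P <- matrix(P, ncol = length(object$experts))
  as.numeric(P %*% object$weights)
}
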