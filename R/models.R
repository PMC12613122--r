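#' Single-model specification
#'
#' Declares one of the six supported regressor families together with its
#' hyperparameter search budget and seed. When `params` is supplied the
#' search is skipped and the model is fitted with exactly those
#' hyperparameters; otherwise a seeded random search over the family's
#' default space (see [default_search_space()]) maximizes the cross-validated
#' R2 objective.
#'
#' @param family one of `"svr"`, `"krr"`, `"gpr"`, `"xgb"`, `"rfr"`, `"knr"`
#' @param budget number of search trials (>= 1)
#' @param seed integer seed controlling sampling, folds and stochastic fits
#' @param params optional named list of fixed hyperparameters
#' @param objective `"cv5"` (5-fold cross-validated R2, default) or `"loo"`
#' @param search_space optional replacement search space
#' @return a `model_spec`
#' @export
model_spec <- function(family = c("svr", "krr", "gpr", "xgb", "rfr", "knr"),
                       budget = 30, seed = 1, params = NULL,
                       objective = c("cv5", "loo"), search_space = NULL) {
  family <- match.arg(family)
  objective <- match.arg(objective)
  if (budget < 1) stop("search budget must be >= 1")
  structure(list(family = family, budget = as.integer(budget),
                 seed = as.integer(seed), params = params,
                 objective = objective,
                 search_space = if (is.null(search_space))
                   default_search_space(family) else search_space),
            class = "model_spec")
}

#' Default hyperparameter search spaces
#'
#' Standard small-data ranges for each family; every entry is either a
#' log-uniform or uniform numeric range, an integer range, or a choice set.
#' @param family model family
#' @return named list of parameter descriptors
#' @export
default_search_space <- function(family) {
  switch(family,
    svr = list(cost = list("log", 1e-2, 1e3),
               epsilon = list("log", 1e-4, 1e-1),
               kernel = list("choice", c("radial", "linear", "polynomial"))),
    krr = list(alpha = list("log", 1e-6, 1e1),
               gamma = list("log", 1e-4, 1e2)),
    gpr = list(noise = list("log", 1e-8, 1e-1),
               length_scale = list("log", 1e-2, 1e2)),
    xgb = list(max_depth = list("int", 2, 8),
               eta = list("log", 1e-3, 0.3),
               nrounds = list("int", 50, 500),
               subsample = list("unif", 0.5, 1),
               colsample_bytree = list("unif", 0.5, 1)),
    rfr = list(num_trees = list("int", 50, 500),
               max_depth = list("int", 2, 12),
               mtry_frac = list("unif", 0.2, 1)),
    knr = list(k = list("int", 1, 15),
               weights = list("choice", c("uniform", "distance")),
               p = list("choice", c(1, 2))),
    stop(sprintf("unknown model family '%s'", family)))
}

sample_params <- function(space) {
  lapply(space, function(s) {
    switch(s[[1]],
      log = exp(stats::runif(1, log(s[[2]]), log(s[[3]]))),
      unif = stats::runif(1, s[[2]], s[[3]]),
      int = sample(seq(s[[2]], s[[3]]), 1),
      choice = s[[2]][[sample.int(length(s[[2]]), 1)]],
      stop("unknown search-space entry type"))
  })
}

# --- family backends --------------------------------------------------------

rbf_kernel <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

fit_family <- function(family, X, y, params, seed = 1) {
  fit <- switch(family,
    svr = {
      p <- utils::modifyList(list(cost = 1, epsilon = 0.1, kernel = "radial"),
                             params)
      e1071::svm(x = X, y = y, type = "eps-regression", kernel = p$kernel,
                 cost = p$cost, epsilon = p$epsilon, scale = FALSE)
    },
    krr = {
      p <- utils::modifyList(list(alpha = 1e-3, gamma = 1), params)
      K <- rbf_kernel(X, X, p$gamma)
      diag(K) <- diag(K) + p$alpha
      dual <- tryCatch(solve(K, y), error = function(e) {
        # singular kernel matrix: raise the regularization floor
        diag(K) <- diag(K) + 1e-8
        solve(K, y)
      })
      list(Xtrain = X, dual = dual, gamma = p$gamma)
    },
    gpr = {
      p <- utils::modifyList(list(noise = 1e-4, length_scale = 1), params)
      # kernlab requires the noise variance to exceed 1e-3
      kernlab::gausspr(x = X, y = y, type = "regression",
                       kernel = "rbfdot",
                       kpar = list(sigma = 1 / (2 * p$length_scale^2)),
                       var = max(p$noise, 1.05e-3), scaled = FALSE,
                       fit = FALSE)
    },
    xgb = {
      p <- utils::modifyList(list(max_depth = 4, eta = 0.1, nrounds = 150,
                                  subsample = 1, colsample_bytree = 1),
                             params)
      xgboost::xgboost(x = X, y = y, nrounds = p$nrounds,
                       max_depth = p$max_depth, learning_rate = p$eta,
                       subsample = p$subsample,
                       colsample_bytree = p$colsample_bytree,
                       objective = "reg:squarederror", verbosity = 0,
                       nthreads = 1)
    },
    rfr = {
      p <- utils::modifyList(list(num_trees = 300, max_depth = 0,
                                  mtry_frac = 1 / 3), params)
      ranger::ranger(x = as.data.frame(X), y = y,
                     num.trees = p$num_trees,
                     max.depth = p$max_depth,
                     mtry = max(1L, min(ncol(X),
                                        ceiling(p$mtry_frac * ncol(X)))),
                     seed = seed, num.threads = 1)
    },
    knr = {
      p <- utils::modifyList(list(k = 5, weights = "uniform", p = 2), params)
      list(Xtrain = X, ytrain = y, k = min(p$k, nrow(X)),
           weights = p$weights, p = p$p)
    },
    stop(sprintf("unknown model family '%s'", family)))
  list(family = family, fit = fit)
}

predict_family <- function(obj, X) {
  switch(obj$family,
    svr = as.numeric(stats::predict(obj$fit, X)),
    krr = as.numeric(rbf_kernel(X, obj$fit$Xtrain, obj$fit$gamma) %*%
                       obj$fit$dual),
    gpr = as.numeric(kernlab::predict(obj$fit, X)),
    xgb = as.numeric(stats::predict(obj$fit, X)),
    rfr = as.numeric(stats::predict(obj$fit,
                                    data = as.data.frame(X))$predictions),
    knr = {
      f <- obj$fit
      unname(apply(X, 1, function(x) {
        d <- (rowSums(abs(sweep(f$Xtrain, 2, x))^f$p))^(1 / f$p)
        o <- order(d)[seq_len(f$k)]
        if (f$weights == "uniform") mean(f$ytrain[o])
        else {
          w <- 1 / pmax(d[o], 1e-12)
          sum(w * f$ytrain[o]) / sum(w)
        }
      }))
    })
}

# --- training ---------------------------------------------------------------

row_matrix <- function(rows, columns) {
  missing <- setdiff(columns, names(rows))
  if (length(missing) > 0)
    stop(sprintf("rows are missing descriptor column(s): %s",
                 paste(missing, collapse = ", ")))
  as.matrix(as.data.frame(rows, check.names = FALSE)[columns])
}

cv_folds <- function(n, k) {
  k <- min(k, n)
  split(sample.int(n), rep_len(seq_len(k), n))
}

#' Train one regressor with seeded hyperparameter search
#'
#' Fits the family declared in `spec` on the given rows. Descriptors are
#' min-max normalized with statistics from these rows only (the fitted
#' [fit_normalizer()] spec is stored in the model and reapplied at
#' prediction). Unless fixed hyperparameters were supplied, a seeded random
#' search of `spec$budget` trials maximizes the cross-validated R2; the
#' final model is refit on all rows with the best configuration.
#'
#' @param spec a [model_spec()]
#' @param rows data frame containing the descriptors and the target column
#' @param target name of the target column
#' @param descriptors descriptor columns to use; default: every numeric
#'   column except the target and metadata
#' @param normalize fit and store a min-max normalizer (default `TRUE`);
#'   set `FALSE` when rows are already normalized
#' @return a `trained_model`
#' @export
train_single_model <- function(spec, rows, target = "phi_delta",
                               descriptors = NULL, normalize = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  rows <- as.data.frame(rows, check.names = FALSE)
  if (!target %in% names(rows))
    stop(sprintf("target column '%s' not found", target))
  if (is.null(descriptors))
    descriptors <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
                           c(target, "id", "metal", "source"))
  y <- rows[[target]]
  norm <- NULL
  if (normalize) {
    norm <- suppressWarnings(fit_normalizer(rows[descriptors]))
    Xdf <- apply_normalizer(norm, rows)
  } else {
    Xdf <- rows[descriptors]
  }
  X <- as.matrix(Xdf[descriptors])

  result <- with_local_seed(spec$seed, {
    if (!is.null(spec$params)) {
      best <- spec$params; best_obj <- NA_real_
    } else {
      folds <- if (spec$objective == "loo") as.list(seq_len(nrow(X)))
               else cv_folds(nrow(X), 5)
      trials <- lapply(seq_len(spec$budget), function(t) sample_params(spec$search_space))
      scores <- vapply(trials, function(par) {
        preds <- rep(NA_real_, nrow(X))
        ok <- tryCatch({
          for (f in folds) {
            m <- fit_family(spec$family, X[-f, , drop = FALSE], y[-f], par,
                            seed = spec$seed)
            preds[f] <- predict_family(m, X[f, , drop = FALSE])
          }
          TRUE
        }, error = function(e) FALSE)
        if (!ok || any(!is.finite(preds))) return(-Inf)
        1 - sum((y - preds)^2) / sum((y - mean(y))^2)
      }, numeric(1))
      best <- trials[[which.max(scores)]]
      best_obj <- max(scores)
    }
    list(fit = fit_family(spec$family, X, y, best, seed = spec$seed),
         params = best, objective_value = best_obj)
  })

  structure(list(family = spec$family, fit = result$fit,
                 params = result$params, normalizer = norm,
                 descriptors = descriptors, target = target,
                 seed = spec$seed, budget = spec$budget,
                 objective = spec$objective,
                 objective_value = result$objective_value),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s on %d descriptors (seed %d)\n",
              toupper(x$family), length(x$descriptors), x$seed))
  invisible(x)
}

#' Predict from a trained model
#' @param object a `trained_model`
#' @param newdata data frame carrying the model's descriptor columns
#' @param ... unused
#' @return numeric predictions
#' @export
predict.trained_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata, check.names = FALSE)
  missing <- setdiff(object$descriptors, names(newdata))
  if (length(missing) > 0)
    stop(sprintf("newdata is missing descriptor column(s): %s",
                 paste(missing, collapse = ", ")))
  Xdf <- if (is.null(object$normalizer)) newdata[object$descriptors]
         else apply_normalizer(object$normalizer, newdata)
  predict_family(object$fit, as.matrix(Xdf[object$descriptors]))
}

#' Freeze the tuned hyperparameters of a trained model into a spec
#' @param model a `trained_model`
#' @return a `model_spec` with fixed `params`
#' @export
frozen_spec <- function(model) {
  model_spec(model$family, budget = 1, seed = model$seed,
             params = model$params)
}
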