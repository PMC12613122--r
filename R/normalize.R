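#' Min-max normalization fitted on training data
#'
#' Every descriptor is scaled to \eqn{(x - x_{min}) / (x_{max} - x_{min})}
#' using training-set statistics only. The spin-orbit coupling column is
#' log10-transformed before scaling (with a small floor so that zero-SOC toy
#' inputs stay finite). Constant columns map to 0 and are flagged. Test rows
#' are transformed with the training statistics and are deliberately not
#' clipped, so out-of-range values may fall outside [0, 1].
#'
#' @param rows data frame or matrix of descriptor values (training rows)
#' @param log_columns columns to log10-transform before scaling
#' @param log_floor floor applied before the logarithm
#' @return a `normalization_spec`
#' @export
fit_normalizer <- function(rows, log_columns = "soc", log_floor = 1e-3) {
  rows <- as.data.frame(rows, check.names = FALSE)
  if (nrow(rows) < 2) stop("need at least 2 rows to fit a normalizer")
  bad <- names(rows)[!vapply(rows, is.numeric, logical(1))]
  if (length(bad) > 0)
    stop(sprintf("non-numeric descriptor column(s): %s",
                 paste(bad, collapse = ", ")))
  log_columns <- intersect(log_columns, names(rows))
  for (cl in log_columns) rows[[cl]] <- log10(pmax(rows[[cl]], log_floor))
  mins <- vapply(rows, min, numeric(1))
  maxs <- vapply(rows, max, numeric(1))
  constant <- names(rows)[maxs - mins <= 0]
  if (length(constant) > 0)
    warning(sprintf("constant descriptor column(s) mapped to 0: %s",
                    paste(constant, collapse = ", ")))
  structure(list(columns = names(rows), min = mins, max = maxs,
                 constant = constant, log_columns = log_columns,
                 log_floor = log_floor),
            class = "normalization_spec")
}

#' Apply a fitted normalization to new rows
#' @param spec a `normalization_spec`
#' @param rows data frame with (at least) the spec's columns
#' @return data frame of normalized values, columns in spec order
#' @export
apply_normalizer <- function(spec, rows) {
  stopifnot(inherits(spec, "normalization_spec"))
  rows <- as.data.frame(rows, check.names = FALSE)
  missing <- setdiff(spec$columns, names(rows))
  if (length(missing) > 0)
    stop(sprintf("rows are missing descriptor column(s): %s",
                 paste(missing, collapse = ", ")))
  out <- rows[spec$columns]
  for (cl in spec$log_columns)
    out[[cl]] <- log10(pmax(out[[cl]], spec$log_floor))
  for (cl in spec$columns) {
    rng <- spec$max[[cl]] - spec$min[[cl]]
    out[[cl]] <- if (rng <= 0) rep(0, nrow(out))
                 else (out[[cl]] - spec$min[[cl]]) / rng
  }
  out
}

#' Random 90:10 train/test split
#'
#' Sizes follow round-to-nearest on the training fraction (a 136-row table
#' yields 122 training and 14 test rows); membership is deterministic under
#' a fixed seed.
#'
#' @param table data frame
#' @param ratio training fraction
#' @param seed integer seed
#' @return list `train`, `test` (both preserving the manifest attribute)
#' @export
split_dataset <- function(table, ratio = 0.9, seed = 1) {
  n <- nrow(table)
  if (n == 0) stop("cannot split an empty table")
  n_train <- max(1L, min(n - 1L, as.integer(round(n * ratio))))
  if (n == 1) n_train <- 1L
  idx <- with_local_seed(seed, sample.int(n, n_train))
  carry <- function(rows) {
    out <- table[rows, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "manifest") <- attr(table, "manifest")
    class(out) <- class(table)
    out
  }
  list(train = carry(sort(idx)), test = carry(setdiff(seq_len(n), idx)))
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
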