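# Batch CSV schema shared by the soft sensor, plant simulator and CLI.
BATCH_COLUMNS <- c("time_h", "T_C", "pH", "u1_rpm", "DO_pct", "u2_vvm",
                   "u3_mlh", "P_gL")
FEATURE_COLUMNS <- c("T_C", "pH", "u1_rpm", "DO_pct", "u2_vvm", "u3_mlh")
TARGET_COLUMN <- "P_gL"

#' Fit per-channel min-max normalization statistics
#'
#' Statistics are fitted on training batches only and reused unchanged for
#' cross-validation and test data (no leakage).  Each channel is later
#' mapped affinely so that `min -> -1` and `max -> +1`; out-of-range values
#' map outside `[-1, 1]` without clipping.
#'
#' @param table data frame or matrix of channels (columns).
#' @return Object of class `norm_stats` with named `min` and `max` vectors.
#' @export
fit_normalization <- function(table) {
  tab <- as.data.frame(table)
  mn <- vapply(tab, min, numeric(1))
  mx <- vapply(tab, max, numeric(1))
  bad <- mx <= mn
  if (any(bad)) {
    stop(sprintf("constant channel(s) cannot be normalized: %s",
                 paste(names(tab)[bad], collapse = ", ")), call. = FALSE)
  }
  structure(list(min = mn, max = mx), class = "norm_stats")
}

#' Normalize channels to the [-1, 1] training range
#'
#' @param table data frame/matrix whose columns are a subset of the fitted
#'   channels.
#' @param stats a [fit_normalization()] result.
#' @return Object of the same shape with each channel affinely mapped.
#' @export
normalize_table <- function(table, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  tab <- as.data.frame(table)
  missing <- setdiff(names(tab), names(stats$min))
  if (length(missing)) {
    stop(sprintf("no normalization stats for channel(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(tab)) {
    rng <- stats$max[[nm]] - stats$min[[nm]]
    tab[[nm]] <- 2 * (tab[[nm]] - stats$min[[nm]]) / rng - 1
  }
  if (is.matrix(table)) as.matrix(tab) else tab
}

#' Invert the [-1, 1] normalization for one channel
#'
#' @param values normalized values.
#' @param stats a `norm_stats` object.
#' @param channel channel name.
#' @return Values on the original physical scale.
#' @export
denormalize <- function(values, stats, channel) {
  stopifnot(inherits(stats, "norm_stats"))
  if (!channel %in% names(stats$min)) {
    stop(sprintf("no normalization stats for channel '%s'", channel),
         call. = FALSE)
  }
  rng <- stats$max[[channel]] - stats$min[[channel]]
  (values + 1) / 2 * rng + stats$min[[channel]]
}

#' Stack batches into a regression table
#'
#' One row per 15-min sample: features are the six same-time auxiliary
#' channels (temperature, pH, agitation, dissolved oxygen, airflow, ammonia
#' flow) and the target is product concentration.  Rows are ordered batch
#' by batch, time-ascending within each batch.  With `include_lag = TRUE`
#' the previous product sample `P(t-1)` is appended as a seventh feature
#' (first sample of each batch uses its own `P(0)`), which gives multi-step
#' predictors an autoregressive handle; off by default to match the static
#' six-feature map.
#'
#' @param batches list of batch data frames with the standard schema.
#' @param include_lag add a lagged-product feature column `P_lag`.
#' @return List with matrix `X` and numeric vector `y`.
#' @export
assemble_regression_table <- function(batches, include_lag = FALSE) {
  if (!length(batches)) stop("empty batch list", call. = FALSE)
  if (is.data.frame(batches)) batches <- list(batches)
  xs <- vector("list", length(batches))
  ys <- vector("list", length(batches))
  for (k in seq_along(batches)) {
    b <- as.data.frame(batches[[k]])
    missing <- setdiff(c(FEATURE_COLUMNS, TARGET_COLUMN), names(b))
    if (length(missing)) {
      stop(sprintf("batch %d is missing column(s): %s", k,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    X <- as.matrix(b[, FEATURE_COLUMNS])
    if (include_lag) {
      p <- b[[TARGET_COLUMN]]
      X <- cbind(X, P_lag = c(p[1], p[-length(p)]))
    }
    xs[[k]] <- X
    ys[[k]] <- b[[TARGET_COLUMN]]
  }
  list(X = do.call(rbind, xs), y = unlist(ys, use.names = FALSE))
}

# metrics --------------------------------------------------------------------

check_metric_args <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1L) {
    stop("`actual` and `predicted` must be equal-length, non-empty",
         call. = FALSE)
  }
}

#' Prediction-accuracy metrics
#'
#' Root mean square error, mean absolute error, and mean absolute
#' percentage error.  `mape()` is fractional (no x100 factor) and requires
#' all actual values to be non-zero.
#'
#' @param actual,predicted equal-length numeric vectors.
#' @return Scalar metric value.
#' @export
rmse <- function(actual, predicted) {
  check_metric_args(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' @rdname rmse
#' @export
mae <- function(actual, predicted) {
  check_metric_args(actual, predicted)
  mean(abs(actual - predicted))
}

#' @rdname rmse
#' @export
mape <- function(actual, predicted) {
  check_metric_args(actual, predicted)
  if (any(actual == 0)) {
    stop("`mape` is undefined for zero actual values", call. = FALSE)
  }
  mean(abs(actual - predicted) / abs(actual))
}

# tuning ---------------------------------------------------------------------

#' Default hyperparameter tuning box
#'
#' Coordinate 1 is the penalty parameter `g` in `[1, 10000]`, coordinate 2
#' the RBF width `sigma` in `[0.001, 0.1]` (normalized-feature scale).
#'
#' @return A [search_space()].
#' @export
default_tuning_bounds <- function() {
  search_space(c(1, 0.001), c(10000, 0.1))
}

#' Cross-validation RMSE fitness of one (g, sigma) candidate
#'
#' Fits an LSSVM on the (normalized) training table and returns the RMSE
#' of its predictions on the (normalized) cross-validation table.  A
#' numerical failure during fitting yields a worst-case sentinel so a
#' surrounding optimizer routes around the candidate instead of crashing.
#'
#' @param candidate numeric vector `c(g, sigma)`.
#' @param train_table,cv_table lists with `X` and `y` on the normalized
#'   scale (see [assemble_regression_table()] / [normalize_table()]).
#' @return Scalar fitness (normalized-scale RMSE).
#' @export
cv_fitness <- function(candidate, train_table, cv_table) {
  g <- candidate[1]; sigma <- candidate[2]
  out <- tryCatch({
    m <- lssvm_fit(train_table$X, train_table$y, g = g, sigma = sigma)
    rmse(cv_table$y, predict(m, cv_table$X))
  }, error = function(e) WORST_FITNESS)
  if (!is.finite(out)) WORST_FITNESS else out
}

new_soft_sensor <- function(model, stats, feature_names, target_name) {
  structure(list(model = model, stats = stats,
                 feature_names = feature_names, target_name = target_name),
            class = "soft_sensor")
}

#' Predict product concentration on the physical scale
#'
#' Normalizes physical-scale query features with the sensor's training
#' statistics, evaluates the LSSVM, and denormalizes the target back to
#' physical units.
#'
#' @param object a `soft_sensor` (from [tune_soft_sensor()] or
#'   [lssvm_read_json()]).
#' @param newdata matrix or data frame of physical-scale feature rows in
#'   the sensor's feature order (or named columns).
#' @param ... unused.
#' @return Numeric predictions in physical units (g/L).
#' @export
predict.soft_sensor <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  nd <- as.data.frame(newdata)
  if (all(object$feature_names %in% names(nd))) {
    nd <- nd[, object$feature_names, drop = FALSE]
  } else if (ncol(nd) == length(object$feature_names)) {
    names(nd) <- object$feature_names
  } else {
    stop("`newdata` does not match the sensor's feature set", call. = FALSE)
  }
  Xn <- as.matrix(normalize_table(nd, object$stats))
  yn <- predict(object$model, Xn)
  denormalize(yn, object$stats, object$target_name)
}

#' @export
print.soft_sensor <- function(x, ...) {
  cat(sprintf("<soft_sensor: %d features -> %s, %d training rows>\n",
              length(x$feature_names), x$target_name,
              nrow(x$model$train_inputs)))
  invisible(x)
}

#' Tune an LSSVM soft sensor with a population optimizer
#'
#' Identification pipeline: fit normalization statistics on the training
#' batches, normalize all channels to `[-1, 1]`, minimize the
#' cross-validation RMSE over the `(g, sigma)` box with GWO (or the PSO
#' baseline), and refit the final model on the training table at the best
#' hyperparameters.
#'
#' @param train_batches,cv_batches lists of batch data frames (standard
#'   schema); both must be non-empty.
#' @param bounds 2-D [search_space()] over `(g, sigma)`; defaults to
#'   [default_tuning_bounds()].
#' @param opt_config an [optimizer_config()].
#' @param algorithm `"gwo"` (default) or `"pso"`.
#' @param include_lag forward to [assemble_regression_table()].
#' @param subsample keep every `subsample`-th row of the train/cv tables
#'   (1 = all rows); a desk-scale speed knob that does not change the
#'   pipeline.
#' @return Object of class `tuning_result`: `best_g`, `best_sigma`,
#'   `cv_rmse` (normalized scale), `optimizer` result, `sensor` (a
#'   `soft_sensor`), and the normalization `stats`.
#' @export
tune_soft_sensor <- function(train_batches, cv_batches,
                             bounds = default_tuning_bounds(),
                             opt_config = optimizer_config(),
                             algorithm = c("gwo", "pso"),
                             include_lag = FALSE, subsample = 1L) {
  algorithm <- match.arg(algorithm)
  if (!length(train_batches) || !length(cv_batches)) {
    stop("train and cross-validation batch lists must be non-empty",
         call. = FALSE)
  }
  if (bounds$dim != 2L) stop("`bounds` must be 2-D (g, sigma)", call. = FALSE)
  subsample <- assert_count(subsample, "subsample")

  train_tab <- assemble_regression_table(train_batches, include_lag)
  cv_tab <- assemble_regression_table(cv_batches, include_lag)
  if (subsample > 1L) {
    keep_tr <- seq(1L, nrow(train_tab$X), by = subsample)
    keep_cv <- seq(1L, nrow(cv_tab$X), by = subsample)
    train_tab <- list(X = train_tab$X[keep_tr, , drop = FALSE],
                      y = train_tab$y[keep_tr])
    cv_tab <- list(X = cv_tab$X[keep_cv, , drop = FALSE],
                   y = cv_tab$y[keep_cv])
  }

  feature_names <- colnames(train_tab$X)
  full_train <- cbind(as.data.frame(train_tab$X),
                      stats::setNames(data.frame(train_tab$y), TARGET_COLUMN))
  stats <- fit_normalization(full_train)

  norm_xy <- function(tab) {
    Xn <- as.matrix(normalize_table(as.data.frame(tab$X), stats))
    rng <- stats$max[[TARGET_COLUMN]] - stats$min[[TARGET_COLUMN]]
    yn <- 2 * (tab$y - stats$min[[TARGET_COLUMN]]) / rng - 1
    list(X = Xn, y = yn)
  }
  train_n <- norm_xy(train_tab)
  cv_n <- norm_xy(cv_tab)

  minimize <- optimizer_by_name(algorithm)
  res <- minimize(function(cand) cv_fitness(cand, train_n, cv_n),
                  bounds, opt_config)

  best_g <- res$best_position[1]
  best_sigma <- res$best_position[2]
  final <- lssvm_fit(train_n$X, train_n$y, g = best_g, sigma = best_sigma)
  sensor <- new_soft_sensor(final, stats, feature_names, TARGET_COLUMN)

  structure(list(best_g = best_g, best_sigma = best_sigma,
                 cv_rmse = res$best_fitness, optimizer = res,
                 algorithm = algorithm, sensor = sensor, stats = stats),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result: %s, g = %.4g, sigma = %.4g, cv RMSE = %.4g>\n",
              x$algorithm, x$best_g, x$best_sigma, x$cv_rmse))
  invisible(x)
}

#' Evaluate a soft sensor on held-out batches
#'
#' Computes RMSE/MAE/MAPE on the physical scale and, using the sensor's
#' own training statistics, on the normalized scale (MAPE only on the
#' physical scale: the normalized target crosses zero).
#'
#' @param sensor a `soft_sensor`.
#' @param batches list of batch data frames.
#' @return List with `physical` and `normalized` metric blocks plus
#'   per-batch physical metrics.
#' @export
evaluate_soft_sensor <- function(sensor, batches) {
  stopifnot(inherits(sensor, "soft_sensor"))
  if (is.data.frame(batches)) batches <- list(batches)
  include_lag <- "P_lag" %in% sensor$feature_names
  per_batch <- lapply(seq_along(batches), function(k) {
    tab <- assemble_regression_table(batches[k], include_lag)
    pred <- predict(sensor, tab$X)
    list(batch = k,
         rmse = rmse(tab$y, pred), mae = mae(tab$y, pred),
         mape = if (all(tab$y != 0)) mape(tab$y, pred) else NA_real_)
  })
  tab <- assemble_regression_table(batches, include_lag)
  pred <- predict(sensor, tab$X)
  rng <- sensor$stats$max[[TARGET_COLUMN]] - sensor$stats$min[[TARGET_COLUMN]]
  yn <- 2 * (tab$y - sensor$stats$min[[TARGET_COLUMN]]) / rng - 1
  pn <- 2 * (pred - sensor$stats$min[[TARGET_COLUMN]]) / rng - 1
  list(
    physical = list(rmse = rmse(tab$y, pred), mae = mae(tab$y, pred),
                    mape = if (all(tab$y != 0)) mape(tab$y, pred)
                           else NA_real_),
    normalized = list(rmse = rmse(yn, pn), mae = mae(yn, pn)),
    per_batch = per_batch,
    predictions = pred, actual = tab$y)
}
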