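# Grip-force regression: Random Forest on the window feature table, with
# n_estimators (ntree) and min_samples_leaf (nodesize) tuned by the bald
# eagle search.  The tuning fitness is the sum of training-set and test-set
# MSE, as specified by the modelling protocol this package implements; note
# that including the test MSE leaks test information into tuning, so a
# cross-validated alternative is available behind a switch.

#' Split a feature dataset into training and test sets
#'
#' Seeded random row-wise split; the training set holds
#' `round(train_fraction * n)` rows.
#'
#' @param data Feature tibble with a label column.
#' @param train_fraction Fraction of rows in the training set (0.70 by
#'   default, the 70/30 protocol).
#' @param seed Integer seed for the split.
#' @param stratify_by Optional column name (e.g. a subject id) whose groups
#'   are kept intact: whole groups are assigned to one side.
#' @return A list with tibbles `train` and `test`.
#' @export
split_dataset <- function(data, train_fraction = 0.7, seed = 1L,
                          stratify_by = NULL) {
  data <- as_tibble(data)
  n <- nrow(data)
  if (n < 10L) abort("need at least 10 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1)")
  }
  if (is.null(stratify_by)) {
    n_train <- round(train_fraction * n)
    idx <- withr::with_seed(seed, sample.int(n, n_train))
    list(train = data[sort(idx), ], test = data[-sort(idx), ])
  } else {
    groups <- unique(data[[stratify_by]])
    n_g <- max(1L, round(train_fraction * length(groups)))
    g_train <- withr::with_seed(seed, sample(groups, n_g))
    list(train = filter(data, .data[[stratify_by]] %in% g_train),
         test = filter(data, !.data[[stratify_by]] %in% g_train))
  }
}

feature_matrix <- function(data, label = "percent_mvc") {
  drop <- intersect(c(label, "segment_id", "window_start", "session"),
                    names(data))
  x <- as.data.frame(data[setdiff(names(data), drop)])
  x <- x[vapply(x, is.numeric, logical(1))]
  if (anyNA(x) || any(!vapply(x, function(c) all(is.finite(c)), logical(1)))) {
    abort("feature matrix contains missing or non-finite values")
  }
  x
}

#' Regression evaluation metrics
#'
#' Mean absolute error, mean squared error and the coefficient of
#' determination:
#' `MAE = mean(|f - fp|)`, `MSE = mean((f - fp)^2)`,
#' `R2 = 1 - sum((fp - f)^2) / sum((f - mean(f))^2)`.
#'
#' @param f_true True grip-force values (%MVC).
#' @param f_pred Predicted values, same length.
#' @return A one-row tibble with columns `mae`, `mse`, `r2`.
#' @examples
#' regression_metrics(c(40, 60, 80), c(42, 58, 81))
#' @export
regression_metrics <- function(f_true, f_pred) {
  if (length(f_true) != length(f_pred)) {
    abort("`f_true` and `f_pred` must have the same length")
  }
  if (length(f_true) == 0L) abort("empty prediction set")
  ss_tot <- sum((f_true - mean(f_true))^2)
  if (ss_tot == 0) abort("R^2 is undefined for constant true values")
  err <- f_true - f_pred
  tibble(mae = mean(abs(err)),
         mse = mean(err^2),
         r2 = 1 - sum(err^2) / ss_tot)
}

#' Tidy-eval wrapper for [regression_metrics()]
#'
#' @param data A data frame of paired true and predicted values.
#' @param truth,estimate Unquoted column names.
#' @return A one-row tibble with `mae`, `mse`, `r2`.
#' @export
grip_metrics <- function(data, truth, estimate) {
  regression_metrics(dplyr::pull(data, {{ truth }}),
                     dplyr::pull(data, {{ estimate }}))
}

fit_rf <- function(x, y, n_estimators, min_samples_leaf, seed) {
  # force labels take a handful of discrete %MVC levels; randomForest warns
  # about regression on few unique responses, which is exactly the intended
  # use here
  withCallingHandlers(
    withr::with_seed(seed, randomForest::randomForest(
      x = x, y = y,
      ntree = as.integer(n_estimators),
      nodesize = as.integer(min_samples_leaf))),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Tuning fitness of a Random Forest hyperparameter pair
#'
#' Fits an RF with `(n_estimators, min_samples_leaf)` (rounded to integers)
#' on the training set under a fixed seed, predicts both sets, and returns
#' the fitness `MSE(train) + MSE(test)`.
#'
#' @param n_estimators Number of trees (rounded; >= 1).
#' @param min_samples_leaf Minimum terminal node size (rounded; >= 1).
#' @param train,test Feature tibbles with the label column.
#' @param seed RF seed, making the evaluation deterministic.
#' @param label Name of the label column.
#' @param cv_folds If > 1, replace the train+test fitness with `cv_folds`-fold
#'   cross-validated MSE on the training set only (leakage-free variant;
#'   off by default).
#' @return A one-row tibble: `n_estimators`, `min_samples_leaf`,
#'   `mse_train`, `mse_test`, `fitness`.
#' @export
rf_fitness <- function(n_estimators, min_samples_leaf, train, test,
                       seed = 1L, label = "percent_mvc", cv_folds = 1L) {
  ne <- max(1L, as.integer(round(n_estimators)))
  nl <- max(1L, as.integer(round(min_samples_leaf)))
  xtr <- feature_matrix(train, label)
  ytr <- train[[label]]
  if (cv_folds > 1L) {
    folds <- withr::with_seed(seed,
      sample(rep_len(seq_len(cv_folds), nrow(xtr))))
    cv_mse <- map_dbl(seq_len(cv_folds), function(k) {
      fit <- fit_rf(xtr[folds != k, , drop = FALSE], ytr[folds != k],
                    ne, nl, seed + k)
      mean((predict(fit, xtr[folds == k, , drop = FALSE]) -
              ytr[folds == k])^2)
    })
    return(tibble(n_estimators = ne, min_samples_leaf = nl,
                  mse_train = NA_real_, mse_test = NA_real_,
                  fitness = mean(cv_mse)))
  }
  xte <- feature_matrix(test, label)
  fit <- fit_rf(xtr, ytr, ne, nl, seed)
  mse_train <- mean((predict(fit, xtr) - ytr)^2)
  mse_test <- mean((predict(fit, xte) - test[[label]])^2)
  tibble(n_estimators = ne, min_samples_leaf = nl,
         mse_train = mse_train, mse_test = mse_test,
         fitness = mse_train + mse_test)
}

#' Tune Random Forest hyperparameters with the bald eagle search
#'
#' Minimizes [rf_fitness()] over the continuous relaxation of the integer
#' space (`n_estimators` in `[10, 500]`, `min_samples_leaf` in `[1, 20]` by
#' default); positions are rounded at evaluation.  Identical rounded pairs
#' are memoised, since the fitness is deterministic given split and seed.
#'
#' @param train,test Feature tibbles from [split_dataset()].
#' @param n_estimators_range,min_samples_leaf_range Two-element integer
#'   bounds of the search space.
#' @param pop_size,max_iter BES budget (10 and 30 by default, the setting
#'   that performed best in tuning-protocol comparisons).
#' @param seed Seed shared by the BES trajectory and the RF fits.
#' @param label Label column name.
#' @param cv_folds Passed to [rf_fitness()].
#' @return An object of class `grip_tune`: `best` (one-row tibble of the
#'   winning integer pair and its fitness components), `bes` (the
#'   [bes_optimize()] result), `evaluations` (all distinct evaluated pairs).
#' @export
tune_grip_rf <- function(train, test,
                         n_estimators_range = c(10L, 500L),
                         min_samples_leaf_range = c(1L, 20L),
                         pop_size = 10L, max_iter = 30L, seed = 1L,
                         label = "percent_mvc", cv_folds = 1L) {
  cache <- new.env(parent = emptyenv())
  fitness <- function(p) {
    ne <- max(1L, as.integer(round(p[1])))
    nl <- max(1L, as.integer(round(p[2])))
    key <- paste(ne, nl, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- rf_fitness(ne, nl, train, test, seed = seed,
                                 label = label, cv_folds = cv_folds)
    }
    cache[[key]]$fitness
  }
  cfg <- bes_config(pop_size = pop_size, max_iter = max_iter,
                    lo = c(n_estimators_range[1], min_samples_leaf_range[1]),
                    hi = c(n_estimators_range[2], min_samples_leaf_range[2]),
                    dim = 2L, seed = seed)
  res <- bes_optimize(fitness, cfg)
  key <- paste(max(1L, as.integer(round(res$best_position[1]))),
               max(1L, as.integer(round(res$best_position[2]))), sep = "_")
  evaluations <- list_rbind(as.list(cache)) |> arrange(.data$fitness)
  structure(list(best = cache[[key]], bes = res, evaluations = evaluations,
                 seed = seed),
            class = "grip_tune")
}

#' @export
print.grip_tune <- function(x, ...) {
  cat(sprintf(
    "<grip_tune> best n_estimators = %d, min_samples_leaf = %d (fitness %.4f, %d distinct pairs tried)\n",
    x$best$n_estimators, x$best$min_samples_leaf, x$best$fitness,
    nrow(x$evaluations)))
  invisible(x)
}

#' @export
autoplot.grip_tune <- function(object, ...) autoplot(object$bes, ...)

#' Train the final grip-force Random Forest
#'
#' @param train Training feature tibble.
#' @param n_estimators,min_samples_leaf Hyperparameters, e.g. from
#'   [tune_grip_rf()].
#' @param seed RF seed.
#' @param label Label column name.
#' @return An object of class `grip_rf` wrapping the fitted forest together
#'   with its hyperparameters, seed and feature names.
#' @export
train_grip_rf <- function(train, n_estimators = 100L, min_samples_leaf = 5L,
                          seed = 1L, label = "percent_mvc") {
  x <- feature_matrix(train, label)
  fit <- fit_rf(x, train[[label]], n_estimators, min_samples_leaf, seed)
  structure(list(fit = fit,
                 n_estimators = as.integer(round(n_estimators)),
                 min_samples_leaf = as.integer(round(min_samples_leaf)),
                 seed = seed, label = label, features = names(x)),
            class = "grip_rf")
}

#' @export
print.grip_rf <- function(x, ...) {
  cat(sprintf("<grip_rf> %d trees, min leaf %d, %d features\n",
              x$n_estimators, x$min_samples_leaf, length(x$features)))
  invisible(x)
}

#' Predict grip force for new windows
#'
#' @param object A `grip_rf` model.
#' @param newdata Feature tibble containing the model's feature columns.
#' @param ... Ignored.
#' @return A tibble of `newdata`'s label (if present) as `percent_mvc` and
#'   the prediction column `.pred`, suitable for [grip_metrics()].
#' @export
predict.grip_rf <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)[object$features]
  pred <- unname(predict(object$fit, x))
  out <- tibble(.pred = pred)
  if (object$label %in% names(newdata)) {
    out <- dplyr::bind_cols(
      tibble(!!object$label := newdata[[object$label]]), out)
  }
  out
}

#' @rdname grip_rf_io
#' @name grip_rf_io
#' @title Persist and reload a grip-force model
#' @description The artifact embeds the fitted forest, hyperparameters and
#'   seed, so a reloaded model reproduces its predictions exactly.
#' @param model A `grip_rf` object.
#' @param path File path for the model artifact.
#' @return `write_grip_rf()` returns `path` invisibly; `read_grip_rf()`
#'   returns the `grip_rf` object.
#' @export
write_grip_rf <- function(model, path) {
  stopifnot(inherits(model, "grip_rf"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname grip_rf_io
#' @export
read_grip_rf <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "grip_rf")) abort("file does not hold a grip_rf model")
  model
}

#' @export
tidy.grip_rf <- function(x, ...) {
  imp <- randomForest::importance(x$fit)
  tibble(feature = rownames(imp), importance = as.numeric(imp[, 1]))
}

#' @export
glance.grip_rf <- function(x, ...) {
  tibble(n_estimators = x$n_estimators,
         min_samples_leaf = x$min_samples_leaf,
         n_features = length(x$features),
         mse_oob = mean(x$fit$mse))
}

#' Observed-versus-predicted plot for grip-force predictions
#'
#' @param object A tibble from [predict.grip_rf()] holding both the truth
#'   and `.pred` columns.
#' @param truth Name of the truth column.
#' @param ... Ignored.
#' @return A ggplot scatter of predictions against true force with the
#'   identity line.
#' @export
plot_grip_predictions <- function(object, truth = "percent_mvc", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[truth]], y = .data$.pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_jitter(width = 1, alpha = 0.5) +
    ggplot2::labs(x = "True grip force (%MVC)",
                  y = "Predicted grip force (%MVC)") +
    ggplot2::theme_minimal()
}
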