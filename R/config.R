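# Run configuration: a validated list binding the per-module settings for
# reproducible end-to-end runs, plus the pipeline driver the command-line
# interface wraps.

#' Default run configuration
#'
#' Assembles the per-module defaults into one validated list: synthetic
#' session settings, band-pass parameters, windowing, the hyperparameter
#' search space, the BES budget, and the train/test split.
#'
#' @param seed Master seed used by every stochastic stage.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  validate_run_config(list(
    seed = as.integer(seed),
    synth = list(channels = 2L, duration_s = 3, rest_s = 1,
                 force_levels = c(100, 80, 60, 40), gamma = 1.5,
                 noise_floor = 0.02, powerline_amp = 0, n_sessions = 2L),
    filter = list(low = 20, high = 490, order = 4, rate = 1000),
    windowing = list(window_ms = 256, step_ms = 56, entropy_bins = 64L),
    split = list(train_fraction = 0.7),
    space = list(n_estimators = c(10L, 500L), min_samples_leaf = c(1L, 20L)),
    bes = list(pop_size = 10L, max_iter = 30L)))
}

#' Validate a run configuration
#'
#' Checks the structural invariants of a [default_run_config()]-shaped list
#' before any computation: positive rates and durations, band edges below
#' Nyquist, window longer than step, a proper split fraction and
#' non-degenerate search bounds.  Errors name the offending field.
#'
#' @param config A named list (e.g. parsed from YAML/JSON).
#' @return The validated config (with class `run_config`), invisibly usable
#'   in pipelines.
#' @export
validate_run_config <- function(config) {
  need <- function(cond, field, msg) {
    if (!cond) abort(sprintf("invalid run config: `%s` %s", field, msg))
  }
  need(is.list(config), "config", "must be a list")
  for (f in c("seed", "synth", "filter", "windowing", "split", "space", "bes")) {
    need(!is.null(config[[f]]), f, "is missing")
  }
  w <- config$windowing
  need(w$step_ms > 0, "windowing.step_ms", "must be positive")
  need(w$window_ms > w$step_ms, "windowing.window_ms",
       "must exceed windowing.step_ms")
  need(w$entropy_bins >= 2, "windowing.entropy_bins", "must be >= 2")
  fl <- config$filter
  need(fl$rate > 0, "filter.rate", "must be positive")
  need(fl$low > 0 && fl$low < fl$high, "filter.low",
       "must satisfy 0 < low < high")
  need(fl$high < fl$rate / 2, "filter.high", "must be below Nyquist")
  sp <- config$split
  need(sp$train_fraction > 0 && sp$train_fraction < 1,
       "split.train_fraction", "must be in (0, 1)")
  sc <- config$space
  need(sc$n_estimators[1] >= 1 && sc$n_estimators[1] < sc$n_estimators[2],
       "space.n_estimators", "must be an increasing range with lo >= 1")
  need(sc$min_samples_leaf[1] >= 1 &&
         sc$min_samples_leaf[1] < sc$min_samples_leaf[2],
       "space.min_samples_leaf", "must be an increasing range with lo >= 1")
  b <- config$bes
  need(b$pop_size >= 1, "bes.pop_size", "must be >= 1")
  need(b$max_iter >= 1, "bes.max_iter", "must be >= 1")
  sy <- config$synth
  need(sy$duration_s > 0, "synth.duration_s", "must be positive")
  need(all(sy$force_levels > 0 & sy$force_levels <= 100),
       "synth.force_levels", "must lie in (0, 100]")
  need(sy$n_sessions >= 1, "synth.n_sessions", "must be >= 1")
  structure(config, class = c("run_config", "list"))
}

#' Read a run configuration from YAML or JSON
#'
#' The format is chosen by file extension (`.yml`/`.yaml` or `.json`);
#' missing fields are filled from [default_run_config()] and the result is
#' validated.
#'
#' @param path Path to the config file.
#' @param seed Fallback seed when the file does not set one.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, seed = 1L) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  parsed <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort(sprintf("unsupported config extension: %s (use .yaml or .json)", path))
  }
  base <- unclass(default_run_config(seed))
  merged <- utils::modifyList(base, parsed)
  validate_run_config(merged)
}

#' Write the run manifest
#'
#' Records everything needed to replay a run: the full configuration, its
#' hash, the seed, and package/R versions.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("semgrip")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full grip-force pipeline on synthetic sessions
#'
#' The end-to-end workflow: generate synthetic sessions, reconstruct and
#' preprocess them, extract window features, split 70/30, tune the Random
#' Forest with BES, train the final model on the training set, and evaluate
#' on the held-out test set.
#'
#' @param config A `run_config`, e.g. [default_run_config()].
#' @param verbose Print stage progress.
#' @return A list of class `grip_pipeline`: `features` (the window feature
#'   table), `split`, `tuning` (a `grip_tune`), `model` (a `grip_rf`),
#'   `predictions` (held-out truth and `.pred`) and `report` (one-row tibble
#'   with `mae`, `mse`, `r2`).
#' @examples
#' \donttest{
#' res <- run_grip_pipeline(default_run_config(seed = 1))
#' res$report
#' }
#' @export
run_grip_pipeline <- function(config = default_run_config(), verbose = FALSE) {
  config <- validate_run_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  sy <- config$synth
  scfg <- synth_config(channels = sy$channels, duration_s = sy$duration_s,
                       rest_s = sy$rest_s, force_levels = sy$force_levels,
                       gamma = sy$gamma, noise_floor = sy$noise_floor,
                       powerline_amp = sy$powerline_amp, rate = config$filter$rate,
                       seed = config$seed)
  say("generating %d synthetic session(s)", sy$n_sessions)
  features <- generate_feature_dataset(
    n_sessions = sy$n_sessions, cfg = scfg,
    window_ms = config$windowing$window_ms,
    step_ms = config$windowing$step_ms,
    entropy_bins = config$windowing$entropy_bins)
  say("feature table: %d windows", nrow(features))
  split <- split_dataset(features, config$split$train_fraction,
                         seed = config$seed)
  say("tuning RF with BES (pop %d, %d iterations)",
      config$bes$pop_size, config$bes$max_iter)
  tuning <- tune_grip_rf(split$train, split$test,
                         n_estimators_range = config$space$n_estimators,
                         min_samples_leaf_range = config$space$min_samples_leaf,
                         pop_size = config$bes$pop_size,
                         max_iter = config$bes$max_iter,
                         seed = config$seed)
  model <- train_grip_rf(split$train,
                         n_estimators = tuning$best$n_estimators,
                         min_samples_leaf = tuning$best$min_samples_leaf,
                         seed = config$seed)
  predictions <- predict(model, split$test)
  report <- grip_metrics(predictions, .data$percent_mvc, .data$.pred)
  say("held-out R^2 = %.4f", report$r2)
  structure(list(features = features, split = split, tuning = tuning,
                 model = model, predictions = predictions, report = report,
                 config = config),
            class = "grip_pipeline")
}

#' @export
print.grip_pipeline <- function(x, ...) {
  cat(sprintf(
    "<grip_pipeline> %d windows; best RF (%d trees, leaf %d); held-out MAE %.4f, MSE %.4f, R2 %.4f\n",
    nrow(x$features), x$model$n_estimators, x$model$min_samples_leaf,
    x$report$mae, x$report$mse, x$report$r2))
  invisible(x)
}
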