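# Shared helpers: independent oracles and small signal utilities used across
# the suite.  Oracles deliberately take a different computational path from
# the package code they check.

# amplitude of the f-Hz component of y, by quadrature projection (exact for
# a pure tone over an integer number of cycles)
tone_amplitude <- function(y, f, rate) {
  t <- (seq_along(y) - 1) / rate
  2 * sqrt(mean(y * sin(2 * pi * f * t))^2 + mean(y * cos(2 * pi * f * t))^2)
}

# loop-accumulated regression metrics: the direct-formula oracle for
# MAE / MSE / R^2
metrics_oracle <- function(f_true, f_pred) {
  n <- length(f_true)
  mae <- 0; mse <- 0
  for (i in seq_len(n)) {
    mae <- mae + abs(f_true[i] - f_pred[i])
    mse <- mse + (f_true[i] - f_pred[i])^2
  }
  fm <- 0
  for (i in seq_len(n)) fm <- fm + f_true[i]
  fm <- fm / n
  ss_res <- 0; ss_tot <- 0
  for (i in seq_len(n)) {
    ss_res <- ss_res + (f_pred[i] - f_true[i])^2
    ss_tot <- ss_tot + (f_true[i] - fm)^2
  }
  list(mae = mae / n, mse = mse / n, r2 = 1 - ss_res / ss_tot)
}

# loop-accumulated time-domain feature oracles
iemg_oracle <- function(x) { s <- 0; for (v in x) s <- s + v; s / length(x) }
rms_oracle <- function(x) { s <- 0; for (v in x) s <- s + v * v; sqrt(s / length(x)) }
wl_oracle <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s
}

# a tiny preprocessed-segments tibble built directly (bypassing
# preprocess_session) for feature-layer tests
make_segments <- function(normalized, filtered, rate = 1000,
                          channels = names(normalized),
                          percent_mvc = 50) {
  purrr::list_rbind(purrr::map(seq_along(normalized), function(i) {
    tibble::tibble(channel = channels[i], segment_id = 1L,
                   percent_mvc = percent_mvc, rate = rate,
                   filtered = list(filtered[[i]]),
                   normalized = list(normalized[[i]]))
  }))
}

# small, quick synthetic feature dataset shared by model-layer tests
quick_feature_dataset <- function(seed = 42, n_sessions = 1L,
                                  duration_s = 2) {
  generate_feature_dataset(
    n_sessions = n_sessions,
    cfg = synth_config(seed = seed, duration_s = duration_s, rest_s = 0.5))
}
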