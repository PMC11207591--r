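# Synthetic acquisition sessions.  Surface EMG is emulated as
# amplitude-modulated band-limited (20-490 Hz) Gaussian noise -- the standard
# stochastic surrogate -- with activation amplitude growing as a power law of
# grip force relative to MVC.  Sessions reproduce the acquisition chain:
# volts on a 1.65 V baseline, 12-bit quantization at 1000 Hz, and
# packetization into the 116-byte transfer protocol (one terminal per
# channel, each with its own MAC).

#' Synthetic-session configuration
#'
#' @param channels Number of sEMG channels (terminals).
#' @param rate Sampling rate in Hz.
#' @param duration_s Contraction duration in seconds.
#' @param force_levels Contraction levels in %MVC, strongest first.
#' @param gamma Activation nonlinearity: contraction amplitude scales as
#'   `(level / 100)^gamma`.  1.5 interpolates between a linear and a strongly
#'   nonlinear EMG-force relation.
#' @param noise_floor Resting/measurement white-noise amplitude, relative to
#'   the MVC-level RMS.
#' @param powerline_amp Optional 50 Hz line interference amplitude, relative
#'   to the MVC-level RMS (0 disables it).
#' @param mvc_rms_v RMS of the MVC-level signal in volts (before baseline);
#'   0.30 V keeps Gaussian excursions comfortably inside the ADC range.
#' @param channel_gain Per-channel relative gain (recycled), emulating the
#'   differing activation of the two forearm muscles.
#' @param ramp_ms Raised-cosine onset/offset ramp of each contraction.
#' @param rest_s Rest gap between contractions, in seconds.
#' @param adc An [adc_config()].
#' @param protocol A [protocol_config()].
#' @param seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(channels = 2L, rate = 1000, duration_s = 3,
                         force_levels = c(100, 80, 60, 40), gamma = 1.5,
                         noise_floor = 0.02, powerline_amp = 0,
                         mvc_rms_v = 0.30, channel_gain = c(1, 0.85),
                         ramp_ms = 200, rest_s = 1,
                         adc = adc_config(), protocol = protocol_config(),
                         seed = NULL) {
  if (gamma <= 0) abort("`gamma` must be positive")
  if (any(force_levels <= 0 | force_levels > 100)) {
    abort("force levels must lie in (0, 100] %MVC")
  }
  structure(list(channels = as.integer(channels), rate = rate,
                 duration_s = duration_s, force_levels = force_levels,
                 gamma = gamma, noise_floor = noise_floor,
                 powerline_amp = powerline_amp, mvc_rms_v = mvc_rms_v,
                 channel_gain = rep_len(channel_gain, channels),
                 ramp_ms = ramp_ms, rest_s = rest_s,
                 adc = adc, protocol = protocol, seed = seed),
            class = "synth_config")
}

# band-limited unit-RMS Gaussian noise, shaped by the sEMG band-pass
shaped_noise <- function(n, rate) {
  x <- bandpass_filter(rnorm(n + 400L), rate = rate)
  x <- x[201:(200 + n)]
  x / sqrt(mean(x^2))
}

raised_cosine_ramp <- function(n, ramp) {
  env <- rep(1, n)
  if (ramp > 0 && 2 * ramp <= n) {
    up <- 0.5 - 0.5 * cos(pi * (seq_len(ramp)) / ramp)
    env[seq_len(ramp)] <- up
    env[(n - ramp + 1):n] <- rev(up)
  }
  env
}

#' Generate one synthetic contraction
#'
#' One contraction at `level` %MVC for every channel: band-limited Gaussian
#' sEMG with amplitude `mvc_rms_v * (level / 100)^gamma * channel_gain`, a
#' raised-cosine onset/offset ramp, an additive white noise floor, and an
#' optional 50 Hz line component.  Values are baseline-removed volts; the
#' 1.65 V baseline is added at digitization ([generate_session()]).
#'
#' @param level Contraction intensity in %MVC, in (0, 100].
#' @param cfg A [synth_config()].  `cfg$seed` (when set) makes the draw
#'   reproducible.
#' @return A tibble with one row per channel: `channel`, `percent_mvc`,
#'   `rate` and a `samples` list-column of volts.
#' @export
generate_contraction <- function(level, cfg = synth_config()) {
  if (level <= 0) abort("`level` must be positive (%MVC)")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- as.integer(round(cfg$duration_s * cfg$rate))
  ramp <- as.integer(round(cfg$ramp_ms * cfg$rate / 1000))
  amp <- cfg$mvc_rms_v * (level / 100)^cfg$gamma
  env <- raised_cosine_ramp(n, ramp)
  tvec <- (0:(n - 1)) / cfg$rate
  tibble(
    channel = paste0("ch", seq_len(cfg$channels)),
    percent_mvc = level,
    rate = cfg$rate,
    samples = map(seq_len(cfg$channels), function(ch) {
      sig <- amp * cfg$channel_gain[ch] * env * shaped_noise(n, cfg$rate) +
        cfg$noise_floor * cfg$mvc_rms_v * rnorm(n)
      if (cfg$powerline_amp > 0) {
        sig <- sig + cfg$powerline_amp * cfg$mvc_rms_v *
          sin(2 * pi * 50 * tvec)
      }
      sig
    }))
}

#' Generate a full synthetic acquisition session
#'
#' Emulates one recording session: an MVC trial first, then one contraction
#' per configured force level, separated by rest gaps (baseline plus noise
#' floor only).  The continuous per-channel signal is digitized (baseline
#' added, 12-bit quantization) and packetized into the transfer protocol,
#' one MAC per channel.
#'
#' @param cfg A [synth_config()]; set `cfg$seed` for reproducibility.
#' @return An object of class `semg_session`:
#'   \describe{
#'     \item{signals}{tibble (`channel`, `mac`, `rate`, `samples`
#'       list-column) of quantized, baseline-removed volts -- what
#'       reconstruction from the packet stream yields.}
#'     \item{truth}{same shape, holding the pre-quantization ground-truth
#'       volts.}
#'     \item{annotations}{tibble (`channel`, `start`, `end`, `percent_mvc`,
#'       `is_mvc`), 0-based half-open sample indices.}
#'     \item{packets}{list of [semg_packet()]s in transmission order,
#'       interleaved across channels.}
#'     \item{cfg}{the configuration used.}
#'   }
#' @examples
#' sess <- generate_session(synth_config(seed = 7))
#' sess$annotations
#' @export
generate_session <- function(cfg = synth_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rate <- cfg$rate
  n_rest <- as.integer(round(cfg$rest_s * rate))
  n_con <- as.integer(round(cfg$duration_s * rate))
  levels <- c(100, cfg$force_levels)  # first contraction is the MVC trial
  is_mvc <- c(TRUE, rep(FALSE, length(cfg$force_levels)))

  chunks <- vector("list", length(levels))
  ann <- vector("list", length(levels))
  pos <- n_rest  # samples emitted so far (one leading rest gap)
  con_cfg <- cfg
  con_cfg$seed <- NULL  # session-level seed governs all draws
  for (k in seq_along(levels)) {
    chunks[[k]] <- generate_contraction(levels[k], con_cfg)
    ann[[k]] <- tibble(start = pos, end = pos + n_con,
                       percent_mvc = levels[k], is_mvc = is_mvc[k])
    pos <- pos + n_con + n_rest
  }
  total <- pos
  floor_sd <- cfg$noise_floor * cfg$mvc_rms_v

  truth <- map(seq_len(cfg$channels), function(ch) {
    x <- floor_sd * rnorm(total)
    for (k in seq_along(levels)) {
      idx <- (ann[[k]]$start + 1):(ann[[k]]$end)
      x[idx] <- chunks[[k]]$samples[[ch]]
    }
    x
  })

  macs <- sprintf("02:00:00:00:00:%02x", seq_len(cfg$channels))
  codes <- map(truth, volts_to_counts, adc = cfg$adc)
  quantized <- map(codes, counts_to_volts, adc = cfg$adc)

  # packetize: pad to a whole number of packets, interleave channels in time
  spp <- cfg$protocol$samples_per_packet
  n_pkt <- ceiling(total / spp)
  packets <- list()
  for (f in seq_len(n_pkt)) {
    for (ch in seq_len(cfg$channels)) {
      idx <- ((f - 1) * spp + 1):min(f * spp, total)
      payload <- codes[[ch]][idx]
      if (length(payload) < spp) {
        payload <- c(payload, rep(volts_to_counts(0, cfg$adc), spp - length(payload)))
      }
      packets[[length(packets) + 1L]] <- semg_packet(macs[ch], f - 1, payload)
    }
  }

  ann_tbl <- list_rbind(ann)
  annotations <- list_rbind(map(paste0("ch", seq_len(cfg$channels)),
                                function(ch) mutate(ann_tbl, channel = ch,
                                                    .before = 1L)))

  structure(list(
    signals = tibble(channel = paste0("ch", seq_len(cfg$channels)),
                     mac = macs, rate = rate, samples = quantized),
    truth = tibble(channel = paste0("ch", seq_len(cfg$channels)),
                   mac = macs, rate = rate, samples = truth),
    annotations = annotations,
    packets = packets,
    cfg = cfg), class = "semg_session")
}

#' @export
print.semg_session <- function(x, ...) {
  cat(sprintf(
    "<semg_session> %d channel(s), %d contraction(s) + MVC trial, %d packets\n",
    x$cfg$channels, length(x$cfg$force_levels), length(x$packets)))
  invisible(x)
}

#' Generate a labeled feature dataset from synthetic sessions
#'
#' Runs the preprocessing and feature-extraction chain on `n_sessions`
#' independent synthetic sessions and stacks the window feature tables; a
#' desk-scale stand-in for a recorded multi-subject dataset.
#'
#' @param n_sessions Number of sessions.
#' @param cfg A [synth_config()]; the session seeds are `cfg$seed + 0 ..
#'   n_sessions - 1` (set `cfg$seed` for reproducibility).
#' @param window_ms,step_ms,entropy_bins Passed to [extract_features()].
#' @return A feature tibble with an extra `session` column.
#' @export
generate_feature_dataset <- function(n_sessions = 2L, cfg = synth_config(),
                                     window_ms = 256, step_ms = 56,
                                     entropy_bins = 64L) {
  list_rbind(map(seq_len(n_sessions), function(s) {
    scfg <- cfg
    if (!is.null(cfg$seed)) scfg$seed <- cfg$seed + s - 1L
    sess <- generate_session(scfg)
    prep <- preprocess_session(sess$signals, sess$annotations)
    extract_features(prep, window_ms = window_ms, step_ms = step_ms,
                     entropy_bins = entropy_bins) |>
      mutate(session = s)
  }))
}
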