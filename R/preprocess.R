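# Preprocessing: segmentation, zero-phase band-pass filtering, full-wave
# rectification, and MVC normalization of reconstructed sEMG.

#' Design the sEMG band-pass filter
#'
#' Butterworth band-pass of prototype order `order` (so the realized filter
#' has order `2 * order`), 20-490 Hz by default -- the fundamental band of
#' surface EMG at a 1000 Hz sampling rate.
#'
#' @param rate Sampling rate in Hz.
#' @param low,high Band edges in Hz; `high` must be below `rate / 2`.
#' @param order Prototype order of the band-pass design.
#' @return A `signal::Arma` filter object.
#' @export
semg_filter_design <- function(rate = 1000, low = 20, high = 490, order = 4) {
  if (high >= rate / 2) {
    abort(sprintf("high edge (%g Hz) must be below the Nyquist frequency (%g Hz)",
                  high, rate / 2))
  }
  if (low <= 0 || low >= high) abort("band edges must satisfy 0 < low < high")
  signal::butter(order, c(low, high) / (rate / 2), type = "pass")
}

#' Squared magnitude response of a digital filter
#'
#' The analytic gain of the zero-phase (forward-backward) realization of a
#' filter at given frequencies: the squared modulus of its transfer function
#' on the unit circle.  Used as the independent oracle for the band-pass
#' stage.
#'
#' @param filt A `signal::Arma` filter (fields `b`, `a`).
#' @param freq Frequencies in Hz at which to evaluate.
#' @param rate Sampling rate in Hz.
#' @return Numeric vector of squared magnitude gains.
#' @export
filter_gain_squared <- function(filt, freq, rate) {
  vapply(freq, function(f) {
    z <- exp(-1i * 2 * pi * f / rate * (seq_along(filt$b) - 1))
    zb <- sum(filt$b * z)
    za <- sum(filt$a * exp(-1i * 2 * pi * f / rate * (seq_along(filt$a) - 1)))
    Mod(zb / za)^2
  }, numeric(1))
}

# Forward-backward filtering with odd-reflection padding at both ends.
# Pad length 3 * max(length(a), length(b)) removes edge transients; the net
# phase response is zero and the net gain is the squared magnitude response.
filtfilt_reflect <- function(filt, x) {
  np <- 3L * max(length(filt$a), length(filt$b))
  n <- length(x)
  if (n <= np) {
    abort(sprintf("segment too short for zero-phase filtering: %d samples, need > %d",
                  n, np))
  }
  pre <- 2 * x[1] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  xp <- c(pre, x, post)
  # start each pass in steady state for the edge level (filter the edge-level
  # deviation, then add back the DC response), so a constant offset produces
  # no start-up transient
  h0 <- sum(filt$b) / sum(filt$a)
  run <- function(z) {
    as.numeric(signal::filter(filt, z - z[1])) + h0 * z[1]
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[(np + 1L):(np + n)]
}

#' Zero-phase band-pass filter an sEMG segment
#'
#' Applies the Butterworth band-pass forward and backward (zero net phase,
#' squared magnitude gain) with odd-reflection edge padding, preserving
#' signal length.
#'
#' @param x Numeric sample vector (volts or mV).
#' @param rate Sampling rate in Hz.
#' @param low,high,order Passed to [semg_filter_design()].
#' @return Filtered numeric vector, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' y <- bandpass_filter(sin(2 * pi * 100 * t), rate = 1000)
#' @export
bandpass_filter <- function(x, rate = 1000, low = 20, high = 490, order = 4) {
  filt <- semg_filter_design(rate, low, high, order)
  filtfilt_reflect(filt, x)
}

#' Full-wave rectification
#'
#' Flips negative values of the zero-mean filtered sEMG above the baseline:
#' elementwise absolute value.
#'
#' @param x Numeric vector.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(x)

#' Peak of a rectified MVC trial
#'
#' The per-subject, per-channel normalization reference: the maximum of the
#' rectified, filtered maximum-voluntary-contraction trial.
#'
#' @param x Rectified sample vector (or several trials concatenated).
#' @return A single positive value, `sEMG_MVC`.
#' @export
mvc_peak <- function(x) {
  if (length(x) == 0L) abort("empty MVC trial")
  m <- max(x)
  if (!is.finite(m) || m <= 0) {
    abort("MVC peak must be positive; got a non-positive or non-finite trial")
  }
  m
}

#' MVC-normalize a rectified segment
#'
#' Scales each sample to percent of the subject's MVC reference:
#' `x / semg_mvc * 100`.
#'
#' @param x Rectified sample vector.
#' @param semg_mvc Positive MVC reference from [mvc_peak()].
#' @return Samples in %MVC units.
#' @export
normalize_mvc <- function(x, semg_mvc) {
  if (!is.finite(semg_mvc) || semg_mvc <= 0) {
    abort("`semg_mvc` must be a positive finite value")
  }
  x / semg_mvc * 100
}

#' Cut annotated segments out of a continuous signal
#'
#' Segments are half-open `[start, end)` in 0-based sample indices, matching
#' the manual start/end calibration of valid contraction segments.
#'
#' @param x Numeric sample vector for one channel.
#' @param annotations A data frame with columns `start`, `end` (0-based,
#'   half-open) and optionally `percent_mvc`.
#' @return A tibble with one row per annotation: `segment_id`, `start`,
#'   `end`, `percent_mvc` (NA when absent) and a `samples` list-column.
#' @examples
#' seg <- segment_signal(rnorm(1000),
#'                       data.frame(start = 100, end = 300, percent_mvc = 60))
#' lengths(seg$samples)  # 200
#' @export
segment_signal <- function(x, annotations) {
  ann <- as_tibble(annotations)
  if (nrow(ann) == 0L) {
    return(tibble(segment_id = integer(), start = numeric(), end = numeric(),
                  percent_mvc = numeric(), samples = list()))
  }
  if (!all(c("start", "end") %in% names(ann))) {
    abort("annotations need `start` and `end` columns")
  }
  if (any(ann$start < 0) || any(ann$end > length(x)) ||
      any(ann$start >= ann$end)) {
    abort("annotation out of range: need 0 <= start < end <= length(x)")
  }
  ann |>
    mutate(segment_id = row_number(),
           percent_mvc = if ("percent_mvc" %in% names(ann))
             .data$percent_mvc else NA_real_,
           samples = map2(.data$start, .data$end,
                          function(s, e) x[(s + 1):e])) |>
    select("segment_id", "start", "end", "percent_mvc", "samples")
}

#' Preprocess one session of reconstructed signals
#'
#' Runs the full chain -- segmentation, zero-phase band-pass filtering,
#' full-wave rectification and MVC normalization -- per channel.  The MVC
#' reference is the peak of the rectified filtered MVC trial(s) of the same
#' channel.  Both the normalized (rectified, %MVC) and the filtered
#' unrectified version of every task segment are retained: time-domain
#' features read the former, spectral features need the unfolded spectrum of
#' the latter.
#'
#' @param signals A tibble with columns `channel`, `rate` and a `samples`
#'   list-column (e.g. from [recording_signals()] or a synthetic session).
#' @param annotations A data frame with columns `channel`, `start`, `end`,
#'   `percent_mvc` and logical `is_mvc` marking the MVC trial(s).
#' @param low,high,order Band-pass parameters, see [bandpass_filter()].
#' @return A list of class `semg_preprocessed`:
#'   \describe{
#'     \item{segments}{tibble, one row per task segment per channel, with
#'       `filtered` and `normalized` list-columns plus `channel`,
#'       `segment_id`, `percent_mvc`, `rate`.}
#'     \item{context}{tibble with `channel` and `semg_mvc` (the
#'       normalization reference, in the units of the input signal).}
#'   }
#' @export
preprocess_session <- function(signals, annotations,
                               low = 20, high = 490, order = 4) {
  signals <- as_tibble(signals)
  ann <- as_tibble(annotations)
  stopifnot(all(c("channel", "rate", "samples") %in% names(signals)))
  if (nrow(ann) == 0L) {
    return(structure(list(
      segments = tibble(channel = character(), segment_id = integer(),
                        percent_mvc = numeric(), rate = numeric(),
                        filtered = list(), normalized = list()),
      context = tibble(channel = character(), semg_mvc = numeric())),
      class = "semg_preprocessed"))
  }
  if (!"is_mvc" %in% names(ann)) ann$is_mvc <- FALSE
  out <- purrr::map(seq_len(nrow(signals)), function(i) {
    chan <- signals$channel[i]
    x <- signals$samples[[i]]
    rate <- signals$rate[i]
    cann <- filter(ann, .data$channel == chan)
    mvc_ann <- filter(cann, .data$is_mvc)
    if (nrow(mvc_ann) == 0L) {
      abort(sprintf("channel %s has no MVC annotation", chan))
    }
    mvc_segs <- segment_signal(x, mvc_ann)
    mvc_rect <- unlist(map(mvc_segs$samples, function(s) {
      rectify(bandpass_filter(s, rate, low, high, order))
    }))
    ref <- mvc_peak(mvc_rect)
    task <- segment_signal(x, filter(cann, !.data$is_mvc))
    chan_rate <- rate
    segs <- task |>
      mutate(channel = chan, rate = chan_rate,
             filtered = map(.data$samples, bandpass_filter, rate = chan_rate,
                            low = low, high = high, order = order),
             normalized = map(.data$filtered,
                              function(f) normalize_mvc(rectify(f), ref))) |>
      select("channel", "segment_id", "percent_mvc", "rate",
             "filtered", "normalized")
    list(segments = segs, context = tibble(channel = chan, semg_mvc = ref))
  })
  structure(list(segments = list_rbind(map(out, "segments")),
                 context = list_rbind(map(out, "context"))),
            class = "semg_preprocessed")
}

#' @export
print.semg_preprocessed <- function(x, ...) {
  cat(sprintf("<semg_preprocessed> %d segment(s) across %d channel(s)\n",
              nrow(x$segments), nrow(x$context)))
  invisible(x)
}

#' Simple amplitude-threshold onset detector (plumbing helper)
#'
#' Convenience helper for locating contraction bursts in a continuous
#' rectified signal; the primary segmentation path is manual annotation.
#' A burst starts when the moving-average rectified amplitude exceeds
#' `k` times the resting level and ends when it falls back below.
#'
#' @param x Numeric sample vector.
#' @param rate Sampling rate in Hz.
#' @param window_ms Moving-average window for the detection envelope.
#' @param k Threshold as a multiple of the median envelope level.
#' @return A tibble with columns `start`, `end` (0-based, half-open).
#' @export
detect_bursts <- function(x, rate = 1000, window_ms = 100, k = 3) {
  env <- envelope_smooth(rectify(x - mean(x)), rate, window_ms)
  thr <- k * median(env)
  on <- env > thr
  d <- diff(c(FALSE, on, FALSE))
  tibble(start = which(d == 1) - 1L, end = which(d == -1) - 1L)
}
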