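# Sliding-window feature extraction: four time-domain features (iEMG, RMS,
# waveform length, Shannon entropy) from the rectified-normalized signal and
# two frequency-domain features (median frequency, mean power frequency) from
# the power spectral density of the filtered, unrectified signal.

#' Sliding-window start indices
#'
#' Windows of `window` samples advance by `step` samples from the start of
#' the segment; trailing partial windows are dropped, so the count is
#' `floor((L - W) / S) + 1` (zero when the segment is shorter than one
#' window).
#'
#' @param n Segment length in samples.
#' @param window Window length in samples.
#' @param step Step size in samples.
#' @return Integer vector of 0-based window start indices (may be empty).
#' @examples
#' length(slide_windows(2000, 256, 56))  # 32
#' @export
slide_windows <- function(n, window, step) {
  stopifnot(window > 0, step > 0)
  if (window <= step) abort("window length must exceed the step size")
  if (n < window) return(integer(0))
  seq.int(0L, as.integer(n - window), by = as.integer(step))
}

#' Integrated EMG of a window
#'
#' The area under the rectified curve per unit time: the mean of the window,
#' `(1/N) * sum(x)`.  (The 1/N factor makes this a mean absolute value for a
#' rectified window, not a plain sum.)
#'
#' @param x Rectified sample window.
#' @return A single value in the units of `x`.
#' @export
feat_iemg <- function(x) {
  if (length(x) == 0L) abort("empty window")
  sum(x) / length(x)
}

#' Root-mean-square amplitude of a window
#'
#' `sqrt((1/N) * sum(x^2))` -- the standard sEMG contraction-intensity
#' measure.
#'
#' @param x Sample window.
#' @return A single non-negative value.
#' @export
feat_rms <- function(x) {
  if (length(x) == 0L) abort("empty window")
  sqrt(sum(x^2) / length(x))
}

#' Waveform length of a window
#'
#' Cumulative absolute first difference, `sum(|x[i+1] - x[i]|)` over
#' `i = 1 .. N-1`.
#'
#' @param x Sample window.
#' @return A single non-negative value.
#' @export
feat_wl <- function(x) {
  if (length(x) < 2L) abort("waveform length needs at least 2 samples")
  sum(abs(diff(x)))
}

#' Shannon entropy of a window's amplitude distribution
#'
#' Amplitude histogram over `[min(x), max(x)]` with `bins` equal-width bins;
#' `H = -sum(p * log2(p))` over non-empty bins (with `0 * log(0) = 0`).
#' A constant window occupies a single bin and has zero entropy.
#'
#' @param x Sample window.
#' @param bins Number of histogram bins (>= 2).
#' @return Entropy in bits, in `[0, log2(bins)]`.
#' @export
feat_entropy <- function(x, bins = 64L) {
  if (length(x) == 0L) abort("empty window")
  if (bins < 2L) abort("`bins` must be at least 2")
  if (max(x) == min(x)) return(0)
  edges <- seq(min(x), max(x), length.out = bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

#' One-sided power spectral density of a window
#'
#' Single-taper periodogram with a Hann window: the window is tapered,
#' Fourier transformed, and scaled to power spectral density
#' (`|X|^2 / (rate * sum(w^2))`, doubled at interior frequencies).  Computed
#' on the filtered, unrectified signal so the spectrum is not folded by
#' rectification.
#'
#' @param x Sample window.
#' @param rate Sampling rate in Hz.
#' @param method `"periodogram"` (Hann taper, default) or `"boxcar"` (no
#'   taper).
#' @return A tibble of class `semg_psd` with columns `freq` (0 to Nyquist)
#'   and `psd`.
#' @examples
#' s <- power_spectrum(sin(2 * pi * 100 * (0:255) / 1000), rate = 1000)
#' s$freq[which.max(s$psd)]  # near 100
#' @export
power_spectrum <- function(x, rate,
                           method = c("periodogram", "boxcar")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 2L) abort("spectrum needs at least 2 samples")
  w <- if (method == "periodogram") {
    0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  } else {
    rep(1, n)
  }
  X <- fft(x * w)
  nh <- n %/% 2L
  psd <- Mod(X[1:(nh + 1L)])^2 / (rate * sum(w^2))
  scale2 <- rep(2, nh + 1L)
  scale2[1L] <- 1
  if (n %% 2L == 0L) scale2[nh + 1L] <- 1
  out <- tibble(freq = (0:nh) * rate / n, psd = psd * scale2)
  class(out) <- c("semg_psd", class(out))
  out
}

#' Median frequency of a power spectrum
#'
#' The smallest frequency at which the cumulative power reaches half of the
#' total power, with linear interpolation inside the crossing bin.
#'
#' @param spectrum A tibble with columns `freq` and `psd`
#'   (see [power_spectrum()]).
#' @return Frequency in Hz, within `[0, Nyquist]`.
#' @export
median_frequency <- function(spectrum) {
  psd <- spectrum$psd
  freq <- spectrum$freq
  total <- sum(psd)
  if (total <= 0) abort("median frequency is undefined for zero total power")
  cum <- cumsum(psd)
  half <- total / 2
  k <- which(cum >= half)[1]
  if (k == 1L) return(freq[1L])
  frac <- (half - cum[k - 1L]) / psd[k]
  freq[k - 1L] + frac * (freq[k] - freq[k - 1L])
}

#' Mean power frequency of a power spectrum
#'
#' The power-weighted mean frequency, `sum(f * PSD) / sum(PSD)` on the
#' frequency grid.
#'
#' @inheritParams median_frequency
#' @return Frequency in Hz, within `[0, Nyquist]`.
#' @export
mean_power_frequency <- function(spectrum) {
  total <- sum(spectrum$psd)
  if (total <= 0) abort("mean power frequency is undefined for zero total power")
  sum(spectrum$freq * spectrum$psd) / total
}

# all six features for one window span
window_features <- function(xt, xf, rate, bins, psd_method) {
  s <- power_spectrum(xf, rate, method = psd_method)
  tibble(iemg = feat_iemg(xt),
         rms = feat_rms(xt),
         wl = feat_wl(xt),
         se = feat_entropy(xt, bins),
         mf = median_frequency(s),
         mpf = mean_power_frequency(s))
}

#' Extract the per-window feature table from preprocessed segments
#'
#' Slides a window over every task segment and computes the six features per
#' channel: iEMG, RMS, waveform length and Shannon entropy from the
#' rectified-normalized samples; median frequency and mean power frequency
#' from the power spectral density of the filtered (unrectified) samples of
#' the same window span.  Channels are spread into prefixed columns
#' (`ch1_iemg`, ..., `ch2_mpf`), so one row is one window with its force
#' label.
#'
#' @param preprocessed A `semg_preprocessed` object from
#'   [preprocess_session()], or its `segments` tibble.
#' @param window_ms Window length in milliseconds (256 by default).
#' @param step_ms Step size in milliseconds (56 by default); must be smaller
#'   than `window_ms`.
#' @param entropy_bins Histogram bins for the Shannon entropy.
#' @param psd_method Periodogram taper, see [power_spectrum()].
#' @return A tibble, one row per window: `segment_id`, `window_start`
#'   (0-based sample index within the segment), the channel-prefixed feature
#'   columns, and `percent_mvc`.
#' @examples
#' \donttest{
#' sess <- generate_session(synth_config(seed = 1))
#' prep <- preprocess_session(sess$signals, sess$annotations)
#' feats <- extract_features(prep)
#' }
#' @export
extract_features <- function(preprocessed, window_ms = 256, step_ms = 56,
                             entropy_bins = 64L,
                             psd_method = c("periodogram", "boxcar")) {
  psd_method <- match.arg(psd_method)
  segs <- if (inherits(preprocessed, "semg_preprocessed"))
    preprocessed$segments else as_tibble(preprocessed)
  if (window_ms <= step_ms) {
    abort("`window_ms` must exceed `step_ms`")
  }
  rows <- purrr::map(seq_len(nrow(segs)), function(i) {
    rate <- segs$rate[i]
    W <- as.integer(round(window_ms * rate / 1000))
    S <- as.integer(round(step_ms * rate / 1000))
    xt <- segs$normalized[[i]]
    xf <- segs$filtered[[i]]
    starts <- slide_windows(length(xt), W, S)
    if (length(starts) == 0L) return(NULL)
    feats <- list_rbind(map(starts, function(s0) {
      idx <- (s0 + 1L):(s0 + W)
      window_features(xt[idx], xf[idx], rate, entropy_bins, psd_method)
    }))
    feats |>
      mutate(segment_id = segs$segment_id[i],
             channel = segs$channel[i],
             percent_mvc = segs$percent_mvc[i],
             window_start = starts)
  })
  long <- list_rbind(rows)
  if (is.null(long) || nrow(long) == 0L) {
    return(tibble(segment_id = integer(), window_start = integer(),
                  percent_mvc = numeric()))
  }
  long |>
    tidyr::pivot_wider(id_cols = c("segment_id", "window_start", "percent_mvc"),
                       names_from = "channel",
                       values_from = c("iemg", "rms", "wl", "se", "mf", "mpf"),
                       names_glue = "{channel}_{.value}") |>
    select("segment_id", "window_start",
           dplyr::matches("^ch.*_(iemg|rms|wl|se|mf|mpf)$"),
           "percent_mvc")
}

#' Write a feature table to CSV
#'
#' @param features Feature tibble from [extract_features()].
#' @param path Output CSV path.
#' @return The tibble, invisibly.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(features)
}
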