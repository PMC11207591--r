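# Agreement analysis between two acquisition systems: envelope smoothing,
# lag alignment, cross-correlation coefficient (CCC), relative agreement
# (1 - RE) of RMS features, and the summary statistics reported for
# system-validation experiments.

#' Envelope smoothing by centered moving average
#'
#' Smooths a rectified-normalized signal with a centered moving average of
#' `window_ms`; edges use partial windows, so a constant input stays
#' constant and the output length equals the input length.
#'
#' @param x Numeric sample vector (typically rectified, normalized sEMG).
#' @param rate Sampling rate in Hz.
#' @param window_ms Averaging window in milliseconds (100 by default).
#' @return Smoothed numeric vector, same length as `x`.
#' @export
envelope_smooth <- function(x, rate = 1000, window_ms = 100) {
  w <- max(1L, as.integer(round(window_ms * rate / 1000)))
  as.numeric(zoo::rollapply(zoo::zoo(x), width = w, FUN = mean,
                            align = "center", partial = TRUE))
}

#' Align two series by their cross-correlation lag
#'
#' Shifts `y` by the lag that maximizes its cross-correlation with `x`
#' (computed on demeaned series) and returns the overlapping region of both.
#'
#' @param x,y Numeric vectors (need not be the same length).
#' @param max_lag Largest lag magnitude searched; defaults to the shorter
#'   length minus one.
#' @return A tibble of class `paired_series` with columns `x` and `y`
#'   (the overlap) and attribute `lag`: positive means `y` lags `x` by that
#'   many samples.
#' @examples
#' a <- sin(2 * pi * 3 * seq(0, 1, by = 1e-3))
#' p <- align_series(a, dplyr::lag(a, 25, default = 0))
#' attr(p, "lag")  # 25
#' @export
align_series <- function(x, y, max_lag = NULL) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2L, ny >= 2L)
  if (is.null(max_lag)) max_lag <- min(nx, ny) - 1L
  xd <- x - mean(x); yd <- y - mean(y)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    if (L >= 0) {
      n <- min(nx, ny - L)
      if (n < 2L) return(-Inf)
      sum(xd[1:n] * yd[(1 + L):(L + n)])
    } else {
      n <- min(nx + L, ny)
      if (n < 2L) return(-Inf)
      sum(xd[(1 - L):(n - L)] * yd[1:n])
    }
  }, numeric(1))
  lag <- lags[which.max(cc)]
  if (lag >= 0) {
    n <- min(nx, ny - lag)
    out <- tibble(x = x[1:n], y = y[(1 + lag):(lag + n)])
  } else {
    n <- min(nx + lag, ny)
    out <- tibble(x = x[(1 - lag):(n - lag)], y = y[1:n])
  }
  # lag is how many samples y must be advanced to match x; report the shift
  # of y relative to x (positive: y is delayed)
  attr(out, "lag") <- lag
  class(out) <- c("paired_series", class(out))
  out
}

#' Cross-correlation coefficient of two aligned series
#'
#' The Pearson-type agreement measure
#' `(n * sum(xy) - sum(x) * sum(y)) / sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))`,
#' bounded in `[-1, 1]`.
#'
#' @param x A numeric vector, or a `paired_series` from [align_series()]
#'   (in which case `y` is taken from it).
#' @param y A numeric vector of the same length as `x`.
#' @return A single value in `[-1, 1]`.
#' @examples
#' ccc(c(1, 2, 3), c(2, 4, 6))  # 1
#' @export
ccc <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  n <- length(x)
  if (n < 2L || length(y) != n) {
    abort("`x` and `y` must be equal-length vectors with n >= 2")
  }
  den2 <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  if (den2 <= 0) abort("CCC is undefined when either series has zero variance")
  (n * sum(x * y) - sum(x) * sum(y)) / sqrt(den2)
}

#' Relative agreement of two RMS features
#'
#' `(1 - |x - y| / y) * 100`, in percent, where `y` is the RMS of the
#' reference system and `x` the RMS of the system under test.
#'
#' @param x_rms RMS of the proposed/test system.
#' @param y_rms RMS of the reference system (> 0).
#' @return Agreement in percent (100 when the two agree exactly).
#' @examples
#' relative_agreement(0.0535, 0.0486)  # 89.92 (to two decimals)
#' @export
relative_agreement <- function(x_rms, y_rms) {
  if (any(y_rms <= 0)) abort("reference RMS must be positive")
  (1 - abs(x_rms - y_rms) / y_rms) * 100
}

#' Summary statistics of a set of CCC values
#'
#' @param values Numeric vector of cross-correlation coefficients.
#' @return A one-row tibble with `max`, `min`, `mean` and `sd` (sample
#'   standard deviation, n - 1 denominator; 0 with a warning for a single
#'   value).
#' @export
summarize_ccc <- function(values) {
  if (length(values) == 0L) abort("no CCC values to summarize")
  s <- if (length(values) == 1L) {
    warn("standard deviation of a single CCC value set to 0")
    0
  } else {
    sd(values)
  }
  tibble(max = max(values), min = min(values),
         mean = mean(values), sd = s)
}

#' Agreement report for paired system recordings
#'
#' Convenience wrapper reproducing the validation workflow: envelope-smooth
#' both processed signals, align them, and report the CCC of the aligned
#' envelopes together with the RMS of each signal and their relative
#' agreement.
#'
#' @param x,y Rectified-normalized signals of the test and reference system.
#' @param rate Sampling rate in Hz.
#' @param window_ms Envelope window, see [envelope_smooth()].
#' @return A one-row tibble: `ccc`, `lag`, `rms_x`, `rms_y`, `agreement`.
#' @export
agreement_report <- function(x, y, rate = 1000, window_ms = 100) {
  ex <- envelope_smooth(x, rate, window_ms)
  ey <- envelope_smooth(y, rate, window_ms)
  p <- align_series(ex, ey)
  tibble(ccc = ccc(p),
         lag = attr(p, "lag"),
         rms_x = feat_rms(x),
         rms_y = feat_rms(y),
         agreement = relative_agreement(feat_rms(x), feat_rms(y)))
}
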