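# Sliding-window feature layer: window placement, the six features against
# direct-formula oracles, and the feature-table contract.

test_that("window placement follows floor((L - W) / S) + 1", {
  expect_length(slide_windows(2000, 256, 56), 32L)
  expect_identical(slide_windows(2000, 256, 56)[1:3], c(0L, 56L, 112L))
  expect_identical(max(slide_windows(2000, 256, 56)), 1736L)
  expect_length(slide_windows(256, 256, 56), 1L)
  expect_length(slide_windows(255, 256, 56), 0L)
  expect_error(slide_windows(100, 56, 56), "exceed")
})

test_that("time-domain features match printed examples and scale linearly", {
  expect_equal(feat_iemg(c(1, 2, 3, 4)), 2.5)
  expect_equal(feat_iemg(rep(3.7, 17)), 3.7)
  expect_equal(feat_rms(c(3, 4)), sqrt(12.5))
  expect_equal(feat_rms(rep(-2, 5)), 2)
  expect_equal(feat_wl(c(0, 1, 0, 1)), 3)
  expect_equal(feat_wl(rep(1, 10)), 0)
  mono <- cumsum(runif(20))
  expect_equal(feat_wl(mono), mono[20] - mono[1])
  withr::with_seed(2, x <- abs(rnorm(128)))
  for (k in c(0.5, 2, 10)) {
    expect_equal(feat_iemg(k * x), k * feat_iemg(x))
    expect_equal(feat_rms(k * x), k * feat_rms(x))
    expect_equal(feat_wl(k * x), k * feat_wl(x))
    expect_equal(feat_entropy(k * x), feat_entropy(x))
  }
  expect_error(feat_iemg(numeric()), "empty")
})

test_that("time-domain features agree with loop oracles to 1e-9 relative", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      x <- rnorm(256, sd = runif(1, 0.1, 50))
      expect_equal(feat_iemg(x), iemg_oracle(x), tolerance = 1e-9)
      expect_equal(feat_rms(x), rms_oracle(x), tolerance = 1e-9)
      expect_equal(feat_wl(x), wl_oracle(x), tolerance = 1e-9)
    }
  })
})

test_that("Shannon entropy behaves like a histogram entropy in bits", {
  # uniform over 2^k bins with equal counts -> k bits
  x <- rep(seq(0, 1, length.out = 8), each = 32)
  expect_equal(feat_entropy(x, bins = 8), 3)
  expect_equal(feat_entropy(rep(5, 100)), 0)
  withr::with_seed(3, z <- rnorm(256))
  expect_lte(feat_entropy(z, 64), log2(64))
  expect_gte(feat_entropy(z, 64), 0)
  expect_error(feat_entropy(z, 1), "bins")
})

test_that("the Hann periodogram localizes tones and conserves power", {
  rate <- 1000
  n <- 256
  x <- sin(2 * pi * 100 * (0:(n - 1)) / rate)
  s <- power_spectrum(x, rate)
  expect_equal(s$freq[which.max(s$psd)], 100, tolerance = rate / n)
  expect_true(all(s$psd >= 0))
  expect_identical(s$freq[1], 0)
  expect_identical(max(s$freq), rate / 2)
  # Parseval: integrated PSD of white noise ~ variance (taper-corrected)
  withr::with_seed(8, w <- rnorm(4096))
  sw <- power_spectrum(w, rate)
  total_power <- sum(sw$psd) * rate / length(w)
  expect_equal(total_power, mean(w^2), tolerance = 0.15)
  expect_equal(power_spectrum(rep(0, 64), rate)$psd, rep(0, 33))
})

test_that("median and mean power frequency match closed forms", {
  rate <- 1000
  # pure tone: both within one frequency bin of the tone
  x <- sin(2 * pi * 100 * (0:255) / rate)
  s <- power_spectrum(x, rate)
  bin <- rate / 256
  expect_lt(abs(median_frequency(s) - 100), bin)
  expect_lt(abs(mean_power_frequency(s) - 100), bin)
  # flat density on [0, B]: both B / 2
  B <- 200
  flat <- tibble::tibble(freq = seq(0, 500, by = 1),
                         psd = as.numeric(seq(0, 500, by = 1) <= B))
  expect_equal(median_frequency(flat), B / 2, tolerance = 1)
  expect_equal(mean_power_frequency(flat), B / 2, tolerance = 1)
  # two equal lines: MPF is the midpoint
  two <- tibble::tibble(freq = c(0, 100, 300, 500), psd = c(0, 1, 1, 0))
  expect_equal(mean_power_frequency(two), 200)
  expect_error(median_frequency(tibble::tibble(freq = 0:10, psd = rep(0, 11))),
               "zero total power")
})

test_that("spectral features are scale-invariant, time features 1-homogeneous", {
  withr::with_seed(4, x <- rnorm(256))
  s1 <- power_spectrum(x, 1000)
  s2 <- power_spectrum(3 * x, 1000)
  expect_equal(median_frequency(s1), median_frequency(s2))
  expect_equal(mean_power_frequency(s1), mean_power_frequency(s2))
})

test_that("extract_features yields one row per window with channel-prefixed columns", {
  withr::with_seed(10, {
    xf1 <- rnorm(2000); xf2 <- rnorm(2000)
  })
  segs <- make_segments(
    normalized = list(ch1 = abs(xf1), ch2 = abs(xf2)),
    filtered = list(ch1 = xf1, ch2 = xf2))
  feats <- extract_features(segs)
  expect_identical(nrow(feats), 32L)
  feat_cols <- grep("^ch[12]_", names(feats), value = TRUE)
  expect_length(feat_cols, 12L)
  expect_true(all(c("ch1_iemg", "ch2_mpf", "percent_mvc", "window_start")
                  %in% names(feats)))
  expect_true(all(is.finite(as.matrix(feats[feat_cols]))))
  expect_true(all(feats$ch1_mf <= 500 & feats$ch1_mpf <= 500))
  # deterministic given fixed input
  expect_identical(feats, extract_features(segs))
  # window inherits the segment force label
  expect_identical(unique(feats$percent_mvc), 50)
  expect_error(extract_features(segs, window_ms = 50, step_ms = 56),
               "exceed")
})

test_that("a sub-window segment yields an empty feature table", {
  segs <- make_segments(normalized = list(ch1 = abs(rnorm(100))),
                        filtered = list(ch1 = rnorm(100)))
  expect_identical(nrow(extract_features(segs)), 0L)
})
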