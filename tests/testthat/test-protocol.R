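# Transfer-protocol codec: frame layout, round trips, stream reconstruction
# and ADC arithmetic.

test_that("serialized packets are 116 bytes with the documented layout", {
  cfg <- protocol_config()
  expect_identical(cfg$packet_length, 116L)
  # 50 samples x 2 bytes = 100 payload bytes, plus 2+4+6+2+2 framing
  expect_identical(cfg$samples_per_packet * cfg$bytes_per_sample, 100L)
  p <- semg_packet("aa:bb:cc:dd:ee:ff", 3, rep(2048L, 50))
  bytes <- encode_packet(p)
  expect_length(bytes, 116L)
  expect_identical(bytes[1:2], cfg$header_magic)
  expect_identical(bytes[3:6], as.raw(c(3, 0, 0, 0)))  # little-endian seq
  expect_identical(bytes[7:12], as.raw(c(0xaa, 0xbb, 0xcc, 0xdd, 0xee, 0xff)))
  expect_identical(bytes[113:114], cfg$end_flag_magic)
  expect_identical(bytes[115:116], cfg$trailer_magic)
})

test_that("encode/decode round-trips random valid packets bit-exactly", {
  withr::with_seed(11, {
    for (k in 1:25) {
      p <- semg_packet(as.raw(sample(0:255, 6, replace = TRUE)),
                       sample(0:1e6, 1),
                       sample(0:4095, 50, replace = TRUE))
      q <- decode_packet(encode_packet(p))
      expect_identical(q$mac, p$mac)
      expect_identical(q$frame_seq, p$frame_seq)
      expect_identical(q$samples, p$samples)
    }
  })
})

test_that("malformed frames are rejected with frame-sync/length errors", {
  p <- semg_packet("02:00:00:00:00:01", 0, rep(0L, 50))
  bytes <- encode_packet(p)
  bad <- bytes; bad[1] <- as.raw(0x00)
  expect_error(decode_packet(bad), "frame-sync")
  bad2 <- bytes; bad2[115] <- as.raw(0x00)
  expect_error(decode_packet(bad2), "frame-sync")
  expect_error(decode_packet(bytes[1:100]), "truncated")
  expect_error(semg_packet("02:00:00:00:00:01", -1, rep(0L, 50)),
               "non-negative")
  expect_error(encode_packet(semg_packet("02:00:00:00:00:01", 0,
                                         rep(5000L, 50))),
               "12-bit")
  expect_error(encode_packet(semg_packet("02:00:00:00:00:01", 0, rep(0L, 49))),
               "50")
})

test_that("a one-second stream of 20 packets carries 1000 samples per MAC", {
  pkts <- lapply(0:19, function(f)
    semg_packet("02:00:00:00:00:01", f, rep(1000L, 50)))
  decoded <- decode_stream(encode_stream(pkts))
  rec <- reconstruct_streams(decoded)
  expect_identical(nrow(rec$samples), 1000L)
  expect_identical(rec$sample_rate, 1000)
})

test_that("reconstruction groups by MAC, sorts by frame, keeps first duplicate", {
  mk <- function(mac, f, val) semg_packet(mac, f, rep(val, 50L))
  pkts <- list(mk("02:00:00:00:00:02", 1, 20L),
               mk("02:00:00:00:00:01", 3, 13L),
               mk("02:00:00:00:00:01", 1, 11L),
               mk("02:00:00:00:00:02", 0, 19L),
               mk("02:00:00:00:00:01", 2, 12L),
               mk("02:00:00:00:00:01", 2, 99L))  # duplicate frame 2
  rec <- reconstruct_streams(pkts)
  s1 <- dplyr::filter(rec$samples, mac == "02:00:00:00:00:01")
  expect_identical(unique(s1$frame_seq), c(1, 2, 3))
  # frame order 1,2,3 and keep-first for the duplicated frame
  expect_identical(unique(s1$code), c(11L, 12L, 13L))
  expect_identical(length(unique(rec$samples$mac)), 2L)
  expect_identical(nrow(rec$gaps), 0L)
})

test_that("missing frames are reported as gap runs, not filled", {
  pkts <- lapply(c(1:4, 6:10), function(f)
    semg_packet("02:00:00:00:00:01", f, rep(0L, 50)))
  rec <- reconstruct_streams(pkts)
  expect_identical(rec$gaps$from_seq, 5)
  expect_identical(rec$gaps$to_seq, 5)
  expect_identical(nrow(rec$samples), 9L * 50L)  # gap not interpolated
  # a multi-frame gap run is reported as one interval
  pkts2 <- lapply(c(0, 1, 5, 6), function(f)
    semg_packet("02:00:00:00:00:01", f, rep(0L, 50)))
  g2 <- reconstruct_streams(pkts2)$gaps
  expect_identical(g2$from_seq, 2)
  expect_identical(g2$to_seq, 4)
})

test_that("counts_to_volts maps the 12-bit range to +/- 1.65 V affinely", {
  adc <- adc_config()
  expect_identical(adc$levels, 4096L)
  expect_equal(counts_to_volts(0L), -1.65)
  expect_equal(counts_to_volts(4095L), 1.65)
  expect_equal(counts_to_volts(c(100L, 100L, 100L)),
               rep(100 / 4095 * 3.3 - 1.65, 3))
  # affine and strictly increasing in the code
  codes <- 0:4095
  v <- counts_to_volts(codes)
  expect_true(all(diff(v) > 0))
  expect_equal(diff(v), rep(3.3 / 4095, 4095))
  expect_error(counts_to_volts(4096L), "codes")
  expect_error(counts_to_volts(-1L), "codes")
})

test_that("volts_to_counts inverts counts_to_volts within one LSB", {
  withr::with_seed(5, v <- runif(500, -1.65, 1.65))
  v2 <- counts_to_volts(volts_to_counts(v))
  expect_true(max(abs(v2 - v)) <= 3.3 / 4095)
})

test_that("recording export and channel mapping are tidy", {
  pkts <- lapply(0:1, function(f)
    semg_packet("02:00:00:00:00:01", f, rep(2048L, 50)))
  rec <- reconstruct_streams(pkts)
  sig <- recording_signals(rec)
  expect_identical(sig$channel, "ch1")
  expect_length(sig$samples[[1]], 100L)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_recording_csv(rec, path)
  expect_true(file.exists(path))
  expect_named(out, c("mac", "frame_seq", "sample_index", "code",
                      "millivolts"))
})
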