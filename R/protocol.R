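# Transfer-protocol codec for the wireless sEMG acquisition terminals.
#
# Each terminal streams one packet every 50 ms.  A packet is a fixed 116-byte
# frame: packet header (2), frame header (4), MAC address (6), 50 ADC samples
# of 2 bytes each (100), end-of-data flag (2), packet end (2).  Fifty samples
# every 50 ms gives the 1000 Hz per-channel sampling rate.

#' Transfer-protocol configuration
#'
#' Describes the fixed 116-byte packet frame used by the acquisition
#' terminals.  The field sizes are those of the terminal firmware; the magic
#' byte values and sample endianness are configurable defaults (the firmware
#' constants are not published), so the codec stays bit-exact against any
#' concrete choice.
#'
#' @param header_magic Two-byte packet-header constant (raw vector).
#' @param trailer_magic Two-byte packet-end constant (raw vector).
#' @param end_flag_magic Two-byte end-of-data flag (raw vector).
#' @param samples_per_packet Number of ADC samples per packet.
#' @param bytes_per_sample Bytes per ADC sample (little-endian).
#' @param packet_period_ms Packet period in milliseconds.
#' @param sample_rate Per-channel sampling rate in Hz.  Must equal
#'   `samples_per_packet * 1000 / packet_period_ms`.
#'
#' @return An object of class `protocol_config`.
#' @examples
#' cfg <- protocol_config()
#' cfg$packet_length  # 116
#' @export
protocol_config <- function(header_magic = as.raw(c(0xAA, 0x55)),
                            trailer_magic = as.raw(c(0x0D, 0x0A)),
                            end_flag_magic = as.raw(c(0xFF, 0xFF)),
                            samples_per_packet = 50L,
                            bytes_per_sample = 2L,
                            packet_period_ms = 50,
                            sample_rate = 1000) {
  stopifnot(is.raw(header_magic), length(header_magic) == 2L,
            is.raw(trailer_magic), length(trailer_magic) == 2L,
            is.raw(end_flag_magic), length(end_flag_magic) == 2L)
  samples_per_packet <- as.integer(samples_per_packet)
  bytes_per_sample <- as.integer(bytes_per_sample)
  if (samples_per_packet * 1000 / packet_period_ms != sample_rate) {
    abort(sprintf(
      "samples_per_packet (%d) x packets per second (%g) must equal sample_rate (%g)",
      samples_per_packet, 1000 / packet_period_ms, sample_rate))
  }
  cfg <- list(
    header_magic = header_magic,
    trailer_magic = trailer_magic,
    end_flag_magic = end_flag_magic,
    samples_per_packet = samples_per_packet,
    bytes_per_sample = bytes_per_sample,
    packet_period_ms = packet_period_ms,
    sample_rate = sample_rate,
    frame_header_len = 4L,
    mac_len = 6L)
  cfg$packet_length <- 2L + cfg$frame_header_len + cfg$mac_len +
    samples_per_packet * bytes_per_sample + 2L + 2L
  structure(cfg, class = "protocol_config")
}

#' ADC configuration
#'
#' The on-chip ADC digitizes the conditioned sEMG at 12-bit resolution
#' (4096 levels) against a 3.3 V reference; the analog front end sits the
#' signal on a 1.65 V (VCC/2) baseline so the alternating sEMG stays
#' positive.  Reconstruction subtracts that baseline again.
#'
#' @param bits ADC resolution in bits.
#' @param vref Reference (full-scale) voltage in volts.
#' @param baseline Baseline offset in volts, `vref / 2` by construction.
#' @return An object of class `adc_config`.
#' @examples
#' adc_config()$levels  # 4096
#' @export
adc_config <- function(bits = 12L, vref = 3.3, baseline = vref / 2) {
  bits <- as.integer(bits)
  stopifnot(bits >= 1L, vref > 0)
  structure(list(bits = bits, levels = as.integer(2^bits), vref = vref,
                 baseline = baseline),
            class = "adc_config")
}

#' Construct a protocol packet
#'
#' @param mac Terminal MAC address: either a 6-byte raw vector or a string
#'   such as `"02:00:00:00:00:01"`.
#' @param frame_seq Non-negative frame sequence number carried in the 4-byte
#'   frame header.
#' @param samples Integer vector of ADC codes, each in `[0, 4095]`; length
#'   must match `samples_per_packet` of the protocol configuration in use.
#' @return An object of class `semg_packet`.
#' @examples
#' p <- semg_packet("02:00:00:00:00:01", 0, rep(2048L, 50))
#' @export
semg_packet <- function(mac, frame_seq, samples) {
  mac <- mac_to_raw(mac)
  frame_seq <- as.numeric(frame_seq)
  if (length(frame_seq) != 1L || is.na(frame_seq) || frame_seq < 0 ||
      frame_seq != floor(frame_seq)) {
    abort("`frame_seq` must be a single non-negative integer")
  }
  samples <- as.integer(samples)
  structure(list(mac = mac, frame_seq = frame_seq, samples = samples),
            class = "semg_packet")
}

#' @export
print.semg_packet <- function(x, ...) {
  cat(sprintf("<semg_packet> mac %s, frame %d, %d samples\n",
              raw_to_mac(x$mac), x$frame_seq, length(x$samples)))
  invisible(x)
}

#' Convert between MAC string and raw representations
#'
#' @param mac A MAC address as `"aa:bb:cc:dd:ee:ff"` (case-insensitive) or a
#'   6-byte raw vector (passed through).
#' @return `mac_to_raw()`: a 6-byte raw vector; `raw_to_mac()`: a lower-case
#'   colon-separated string.
#' @examples
#' raw_to_mac(mac_to_raw("02:00:00:00:00:01"))
#' @export
mac_to_raw <- function(mac) {
  if (is.raw(mac)) {
    if (length(mac) != 6L) abort("MAC must be exactly 6 bytes")
    return(mac)
  }
  parts <- strsplit(as.character(mac), ":", fixed = TRUE)[[1]]
  if (length(parts) != 6L || !all(grepl("^[0-9a-fA-F]{1,2}$", parts))) {
    abort(sprintf("cannot parse MAC address '%s'", mac))
  }
  as.raw(strtoi(parts, 16L))
}

#' @rdname mac_to_raw
#' @export
raw_to_mac <- function(mac) {
  stopifnot(is.raw(mac), length(mac) == 6L)
  paste(sprintf("%02x", as.integer(mac)), collapse = ":")
}

# unsigned integer <-> little-endian raw bytes
int_to_le <- function(x, width) {
  x <- as.numeric(x)
  as.raw((x %/% 256^(0:(width - 1))) %% 256)
}

le_to_int <- function(bytes) {
  sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
}

#' Encode a packet to its 116-byte wire form
#'
#' Serializes a [semg_packet()] in wire order: packet header, frame header
#' (little-endian frame sequence), MAC address, the 50 two-byte little-endian
#' ADC samples, end-of-data flag, packet end.
#'
#' @param packet A [semg_packet()].
#' @param cfg A [protocol_config()].
#' @return A raw vector of length `cfg$packet_length` (116 by default).
#' @examples
#' p <- semg_packet("02:00:00:00:00:01", 7, rep(1024L, 50))
#' length(encode_packet(p))  # 116
#' @export
encode_packet <- function(packet, cfg = protocol_config()) {
  stopifnot(inherits(packet, "semg_packet"))
  ns <- length(packet$samples)
  if (ns != cfg$samples_per_packet) {
    abort(sprintf("packet carries %d samples; protocol expects %d",
                  ns, cfg$samples_per_packet))
  }
  smax <- 2L^(8L * cfg$bytes_per_sample) - 1L
  if (anyNA(packet$samples) || any(packet$samples < 0L) ||
      any(packet$samples > 4095L) || any(packet$samples > smax)) {
    abort("ADC samples must be integers in [0, 4095] (12-bit range)")
  }
  sample_bytes <- as.raw(rbind(packet$samples %% 256L,
                               packet$samples %/% 256L))
  c(cfg$header_magic,
    int_to_le(packet$frame_seq, cfg$frame_header_len),
    packet$mac,
    sample_bytes,
    cfg$end_flag_magic,
    cfg$trailer_magic)
}

#' Decode one 116-byte frame into a packet
#'
#' Validates the frame length and the three magic fields, then extracts the
#' frame sequence, MAC address and ADC samples.
#'
#' @param bytes A raw vector holding at least one full frame (extra trailing
#'   bytes are ignored).
#' @param cfg A [protocol_config()].
#' @return A [semg_packet()].
#' @examples
#' p <- semg_packet("02:00:00:00:00:01", 3, rep(0L, 50))
#' identical(decode_packet(encode_packet(p))$frame_seq, p$frame_seq)
#' @export
decode_packet <- function(bytes, cfg = protocol_config()) {
  stopifnot(is.raw(bytes))
  L <- cfg$packet_length
  if (length(bytes) < L) {
    abort(sprintf("truncated frame: %d bytes, protocol frame is %d",
                  length(bytes), L))
  }
  if (!identical(bytes[1:2], cfg$header_magic)) {
    abort("frame-sync error: packet header magic mismatch")
  }
  off <- 2L
  frame_seq <- le_to_int(bytes[(off + 1L):(off + cfg$frame_header_len)])
  off <- off + cfg$frame_header_len
  mac <- bytes[(off + 1L):(off + cfg$mac_len)]
  off <- off + cfg$mac_len
  nbytes <- cfg$samples_per_packet * cfg$bytes_per_sample
  sb <- as.integer(bytes[(off + 1L):(off + nbytes)])
  samples <- sb[seq(1L, nbytes, by = 2L)] + 256L * sb[seq(2L, nbytes, by = 2L)]
  off <- off + nbytes
  if (!identical(bytes[(off + 1L):(off + 2L)], cfg$end_flag_magic)) {
    abort("frame-sync error: end-of-data flag mismatch")
  }
  if (!identical(bytes[(off + 3L):(off + 4L)], cfg$trailer_magic)) {
    abort("frame-sync error: packet-end magic mismatch")
  }
  semg_packet(mac, frame_seq, samples)
}

#' Encode or decode a whole packet stream
#'
#' `encode_stream()` concatenates the wire forms of a list of packets;
#' `decode_stream()` splits a raw byte stream into consecutive 116-byte
#' frames and decodes each.
#'
#' @param packets A list of [semg_packet()] objects.
#' @param bytes A raw vector whose length is a multiple of the frame length.
#' @param cfg A [protocol_config()].
#' @return `encode_stream()`: a raw vector; `decode_stream()`: a list of
#'   packets.
#' @export
encode_stream <- function(packets, cfg = protocol_config()) {
  do.call(c, lapply(packets, encode_packet, cfg = cfg))
}

#' @rdname encode_stream
#' @export
decode_stream <- function(bytes, cfg = protocol_config()) {
  L <- cfg$packet_length
  if (length(bytes) %% L != 0L) {
    abort(sprintf("stream length %d is not a multiple of the %d-byte frame",
                  length(bytes), L))
  }
  lapply(seq_len(length(bytes) %/% L), function(k) {
    decode_packet(bytes[((k - 1L) * L + 1L):(k * L)], cfg)
  })
}

#' Reconstruct per-terminal sample streams from a packet sequence
#'
#' Groups packets by MAC address, orders each group by frame sequence,
#' drops duplicate frames (first occurrence kept) and reports -- but does not
#' fill -- gaps in the frame sequence.  This mirrors the host-side
#' reconstruction step: classify by MAC, then concatenate the sample payloads
#' in frame order.
#'
#' @param packets A list of [semg_packet()] objects, possibly interleaved
#'   across terminals and out of order.
#' @param cfg A [protocol_config()].
#' @return An object of class `semg_recording`: a list with
#'   \describe{
#'     \item{samples}{tibble with columns `mac`, `frame_seq`, `sample_index`
#'       (0-based within the MAC stream) and `code`.}
#'     \item{gaps}{tibble with columns `mac`, `from_seq`, `to_seq`, one row
#'       per missing frame-sequence run.}
#'     \item{sample_rate}{per-channel sampling rate in Hz.}
#'   }
#' @examples
#' pkts <- lapply(c(3, 1, 2), function(s)
#'   semg_packet("02:00:00:00:00:01", s, rep(2048L, 50)))
#' rec <- reconstruct_streams(pkts)
#' head(rec$samples)
#' @export
reconstruct_streams <- function(packets, cfg = protocol_config()) {
  stopifnot(length(packets) > 0L)
  tbl <- tibble(
    mac = vapply(packets, function(p) raw_to_mac(p$mac), character(1)),
    frame_seq = vapply(packets, function(p) p$frame_seq, numeric(1)),
    samples = lapply(packets, function(p) p$samples))
  tbl <- tbl |>
    arrange(.data$mac, .data$frame_seq) |>
    distinct(.data$mac, .data$frame_seq, .keep_all = TRUE)

  samples <- tbl |>
    tidyr::unnest_longer(samples, values_to = "code") |>
    group_by(.data$mac) |>
    mutate(sample_index = row_number() - 1L) |>
    ungroup() |>
    select("mac", "frame_seq", "sample_index", "code")

  gaps <- tbl |>
    group_by(.data$mac) |>
    summarise(gap = list(frame_gaps(.data$frame_seq)), .groups = "drop") |>
    tidyr::unnest("gap")
  if (nrow(gaps) == 0L) {
    gaps <- tibble(mac = character(), from_seq = numeric(),
                   to_seq = numeric())
  }

  structure(list(samples = samples, gaps = gaps,
                 sample_rate = cfg$sample_rate),
            class = "semg_recording")
}

# missing runs between min and max of an increasing frame_seq vector
frame_gaps <- function(seqs) {
  expected <- seq(min(seqs), max(seqs))
  missing <- setdiff(expected, seqs)
  if (length(missing) == 0L) {
    return(tibble(from_seq = numeric(), to_seq = numeric()))
  }
  run_id <- cumsum(c(1, diff(missing) != 1))
  tibble(missing = as.numeric(missing), run = run_id) |>
    group_by(.data$run) |>
    summarise(from_seq = min(.data$missing), to_seq = max(.data$missing),
              .groups = "drop") |>
    select("from_seq", "to_seq")
}

#' @export
print.semg_recording <- function(x, ...) {
  macs <- unique(x$samples$mac)
  cat(sprintf("<semg_recording> %d terminal(s), %d samples total, %g Hz\n",
              length(macs), nrow(x$samples), x$sample_rate))
  if (nrow(x$gaps) > 0) cat(sprintf("  %d frame-sequence gap run(s)\n",
                                    nrow(x$gaps)))
  invisible(x)
}

#' Convert ADC codes to baseline-removed volts
#'
#' Maps a 12-bit code to volts as `code / (2^bits - 1) * vref - baseline`,
#' so code 0 gives -1.65 V, full scale gives +1.65 V, and the analog
#' front-end's VCC/2 offset is removed (baseline returned to 0 V).
#'
#' @param codes Integer vector of ADC codes in `[0, 2^bits - 1]`.
#' @param adc An [adc_config()].
#' @return A numeric vector of volts (multiply by 1000 for mV).
#' @examples
#' counts_to_volts(c(0L, 4095L))  # -1.65, +1.65
#' @export
counts_to_volts <- function(codes, adc = adc_config()) {
  cmax <- adc$levels - 1L
  if (anyNA(codes) || any(codes < 0) || any(codes > cmax)) {
    abort(sprintf("ADC codes must lie in [0, %d]", cmax))
  }
  codes / cmax * adc$vref - adc$baseline
}

#' Inverse of [counts_to_volts()]: quantize volts to ADC codes
#'
#' Adds the baseline back, scales to the code grid, rounds to the nearest
#' code and clips to the valid range -- the digitization the terminal's ADC
#' performs.
#'
#' @param volts Numeric vector of baseline-removed volts.
#' @param adc An [adc_config()].
#' @return Integer ADC codes in `[0, 2^bits - 1]`.
#' @export
volts_to_counts <- function(volts, adc = adc_config()) {
  cmax <- adc$levels - 1L
  code <- round((volts + adc$baseline) / adc$vref * cmax)
  as.integer(pmin(pmax(code, 0), cmax))
}

#' Analog front-end gain arithmetic
#'
#' Total gain of the two-stage amplification chain: a 45x instrumentation
#' preamplifier followed by a 25x second stage, 1125x in total.  Kept as an
#' analytic check of the acquisition arithmetic; the analog hardware itself
#' is outside this package.
#'
#' @param primary First-stage gain.
#' @param secondary Second-stage gain.
#' @return The total gain, `primary * secondary`.
#' @examples
#' acquisition_gain()  # 1125
#' @export
acquisition_gain <- function(primary = 45, secondary = 25) {
  stopifnot(primary > 0, secondary > 0)
  primary * secondary
}

#' Tidy a reconstructed recording into per-channel signals
#'
#' Converts the codes of a [reconstruct_streams()] result to volts and nests
#' one row per terminal, assigning channel labels in MAC order (one terminal
#' is one channel).
#'
#' @param recording A `semg_recording`.
#' @param adc An [adc_config()].
#' @param channel_map Optional named character vector mapping MAC strings to
#'   channel labels; defaults to `ch1`, `ch2`, ... in MAC sort order.
#' @return A tibble with columns `channel`, `mac`, `rate` and a `samples`
#'   list-column of baseline-removed volts.
#' @export
recording_signals <- function(recording, adc = adc_config(),
                              channel_map = NULL) {
  stopifnot(inherits(recording, "semg_recording"))
  macs <- sort(unique(recording$samples$mac))
  if (is.null(channel_map)) {
    channel_map <- stats::setNames(paste0("ch", seq_along(macs)), macs)
  }
  recording$samples |>
    group_by(.data$mac) |>
    summarise(samples = list(counts_to_volts(.data$code, adc)),
              .groups = "drop") |>
    mutate(channel = unname(channel_map[.data$mac]),
           rate = recording$sample_rate) |>
    select("channel", "mac", "rate", "samples") |>
    arrange(.data$channel)
}

#' Export a reconstructed recording as a tidy CSV
#'
#' Writes one row per sample with columns `mac`, `frame_seq`, `sample_index`,
#' `code`, `millivolts`.
#'
#' @param recording A `semg_recording`.
#' @param path Output CSV path.
#' @param adc An [adc_config()].
#' @return The written tibble, invisibly.
#' @export
write_recording_csv <- function(recording, path, adc = adc_config()) {
  out <- recording$samples |>
    mutate(millivolts = counts_to_volts(.data$code, adc) * 1000)
  readr::write_csv(out, path)
  invisible(out)
}
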