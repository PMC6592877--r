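# European Data Format codec.
#
# An EDF file is a fixed 256-byte ASCII header, 256 further ASCII bytes per
# signal, then data records of 16-bit little-endian two's-complement
# integers. Each signal carries an affine digital->physical calibration
# (physical_min/max vs digital_min/max). Continuous EDF only: no EDF+
# discontinuous files, no annotations channel (events live in events.tsv);
# an "EDF Annotations" signal encountered on read is skipped with a warning.

EDF_DIG_MIN <- -32768L
EDF_DIG_MAX <- 32767L

# fixed-header field widths, in order
EDF_FIXED_FIELDS <- c(version = 8L, patient_id = 80L, recording_id = 80L,
                      start_date = 8L, start_time = 8L, header_bytes = 8L,
                      reserved = 44L, n_records = 8L, record_duration = 8L,
                      n_signals = 4L)

# per-signal field widths, in header order (each block holds the field for
# every signal before the next field starts)
EDF_SIGNAL_FIELDS <- c(label = 16L, transducer = 80L, physical_dimension = 8L,
                       physical_min = 8L, physical_max = 8L,
                       digital_min = 8L, digital_max = 8L,
                       prefiltering = 80L, samples_per_record = 8L,
                       reserved = 32L)

# render a number into an EDF ASCII field of `width` bytes; tries shrinking
# precision until it fits
edf_num <- function(x, width = 8L) {
  if (x == round(x) && abs(x) < 10^(width)) {
    s <- sprintf("%d", as.integer(round(x)))
    if (nchar(s) <= width) return(s)
  }
  for (digits in seq(width - 1L, 1L)) {
    s <- trimws(formatC(x, digits = digits, format = "g", width = 0))
    s <- sub("e([+-])0(\\d)$", "e\\1\\2", s)  # e-05 -> e-5
    if (nchar(s) <= width) return(s)
  }
  format_error(sprintf("value %g does not fit an EDF %d-byte numeric field", x, width))
}

edf_pad <- function(s, width) {
  s <- gsub("µ|μ", "u", as.character(s))  # micro sign -> ASCII 'u'
  if (grepl("[^\x20-\x7e]", s, useBytes = TRUE)) {
    s <- iconv(s, to = "ASCII", sub = "?")
  }
  if (nchar(s, type = "bytes") > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Convert an EDF digital sample to its physical value
#'
#' Applies the affine per-signal calibration
#' `p = physical_min + (d - digital_min) * (physical_max - physical_min) /
#' (digital_max - digital_min)`, so `digital_min` maps exactly to
#' `physical_min` and `digital_max` to `physical_max`.
#'
#' @param d Digital sample value(s) (integer-valued).
#' @param physical_min,physical_max Physical calibration range
#'   (`physical_max > physical_min`).
#' @param digital_min,digital_max Digital calibration range (defaults: the
#'   full 16-bit range).
#' @return Physical value(s).
#' @export
digital_to_physical <- function(d, physical_min, physical_max,
                                digital_min = EDF_DIG_MIN,
                                digital_max = EDF_DIG_MAX) {
  if (physical_max <= physical_min || digital_max <= digital_min) {
    invariant_error("calibration ranges must have max > min")
  }
  physical_min + (d - digital_min) * (physical_max - physical_min) /
    (digital_max - digital_min)
}

#' Convert a physical value to its EDF digital sample
#'
#' Inverse of [digital_to_physical()], rounding to the nearest integer and
#' clamping to the digital range.
#'
#' @inheritParams digital_to_physical
#' @param p Physical value(s).
#' @return Integer digital value(s) within `[digital_min, digital_max]`.
#' @export
physical_to_digital <- function(p, physical_min, physical_max,
                                digital_min = EDF_DIG_MIN,
                                digital_max = EDF_DIG_MAX) {
  if (physical_max <= physical_min || digital_max <= digital_min) {
    invariant_error("calibration ranges must have max > min")
  }
  d <- round(digital_min + (p - physical_min) * (digital_max - digital_min) /
               (physical_max - physical_min))
  pmin(pmax(d, digital_min), digital_max)
}

# pick record_duration: 1 s when sfreq * 1 is integral, else the smallest
# k <= 10 making sfreq * k integral
edf_record_duration <- function(sfreq, requested = 1) {
  if (!is.null(requested) && abs(sfreq * requested - round(sfreq * requested)) < 1e-9) {
    return(requested)
  }
  for (k in 1:10) {
    if (abs(sfreq * k - round(sfreq * k)) < 1e-9) return(k)
  }
  format_error(sprintf(
    "sampling frequency %g Hz admits no record duration k <= 10 s with integral samples per record",
    sfreq))
}

#' Write a recording as an EDF file
#'
#' Physical ranges are chosen per channel from the data extrema: symmetric
#' `[-m, m]` with a 1 percent margin (`m = 1.01 * max|x|`, or 1 unit for an
#' all-zero channel), so calibration is never zero-width. The quantization
#' step is therefore `2 m / 65535` per channel. A final partial record is
#' padded with the channel's last sample value and the record count rounded
#' up. Events are not stored in the file (no EDF+ annotations channel);
#' in a BIDS tree they belong in the accompanying events.tsv.
#'
#' @param r An [new_recording()] object.
#' @param path Destination file.
#' @param record_duration Data-record length in seconds (default 1 s);
#'   when `sampling frequency x record_duration` is not an integer the
#'   smallest integral alternative up to 10 s is used instead.
#' @param patient_id,recording_id,start_date,start_time Header strings;
#'   defaults are anonymous with a fixed epoch so output is reproducible.
#' @return Invisibly, the fixed-header field list (including `header_bytes`,
#'   `n_records`, and the per-channel calibration actually written).
#' @export
write_edf <- function(r, path, record_duration = 1,
                      patient_id = "X X X X", recording_id = "Startdate 01-JAN-2000 X X X",
                      start_date = "01.01.00", start_time = "00.00.00") {
  stopifnot(inherits(r, "eeg_recording"))
  rd <- edf_record_duration(r$sfreq, record_duration)
  spr <- as.integer(round(r$sfreq * rd))
  ns <- n_channels(r)
  nsamp <- n_samples(r)
  n_rec <- as.integer(ceiling(nsamp / spr))
  header_bytes <- 256L * (ns + 1L)

  # symmetric physical range with 1% margin; reparse the ASCII rendering so
  # the calibration used for quantization is exactly what the header stores
  m <- apply(abs(r$data), 1, max)
  m <- ifelse(m == 0, 1, 1.01 * m)
  pmax_str <- vapply(m, edf_num, "")
  pmax_hdr <- as.numeric(pmax_str)
  if (any(pmax_hdr <= 0)) {
    precision_warning("physical range collapsed to a non-positive bound")
  }

  fixed <- list(version = "0", patient_id = patient_id, recording_id = recording_id,
                start_date = start_date, start_time = start_time,
                header_bytes = header_bytes, reserved = "",
                n_records = n_rec, record_duration = rd, n_signals = ns)
  fixed_str <- mapply(function(v, w) edf_pad(v, w), fixed, EDF_FIXED_FIELDS)

  sig <- list(label = r$channel_names,
              transducer = rep("", ns),
              physical_dimension = r$channel_units,
              physical_min = paste0("-", pmax_str),
              physical_max = pmax_str,
              digital_min = rep(EDF_DIG_MIN, ns),
              digital_max = rep(EDF_DIG_MAX, ns),
              prefiltering = rep("", ns),
              samples_per_record = rep(spr, ns),
              reserved = rep("", ns))
  sig_str <- unlist(lapply(names(EDF_SIGNAL_FIELDS), function(f) {
    vapply(sig[[f]], edf_pad, "", width = EDF_SIGNAL_FIELDS[[f]])
  }))

  # pad each channel to a whole number of records with its last sample
  total <- n_rec * spr
  padded <- r$data
  if (total > nsamp) {
    padded <- cbind(padded, matrix(padded[, nsamp], ns, total - nsamp))
  }
  dig <- matrix(0L, ns, total)
  for (i in seq_len(ns)) {
    dig[i, ] <- as.integer(physical_to_digital(padded[i, ], -pmax_hdr[i], pmax_hdr[i]))
  }
  # payload order: record-major, then signal, then sample
  arr <- array(0L, dim = c(spr, ns, n_rec))
  for (i in seq_len(ns)) {
    arr[, i, ] <- dig[i, ]
  }

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(c(fixed_str, sig_str), collapse = ""), con, eos = NULL,
            useBytes = TRUE)
  writeBin(as.vector(arr), con, size = 2L, endian = "little")
  invisible(c(fixed, list(samples_per_record = spr,
                          physical_max = pmax_hdr, physical_min = -pmax_hdr)))
}

read_edf_ascii <- function(con, width, n = 1L) {
  raw <- readChar(con, rep(width, n), useBytes = TRUE)
  if (length(raw) < n) format_error("EDF header truncated")
  trimws(raw)
}

edf_header_num <- function(s, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v))) {
    format_error(sprintf("EDF header field %s is not numeric: '%s'",
                         what, s[is.na(v)][1]))
  }
  v
}

#' Read the headers of an EDF file
#'
#' Parses the fixed and per-signal headers without touching the payload.
#'
#' @param path EDF file.
#' @return List with the fixed-header fields plus per-signal vectors
#'   (`label`, `physical_dimension`, `physical_min`, `physical_max`,
#'   `digital_min`, `digital_max`, `samples_per_record`) and the derived
#'   `sfreq` and `n_samples`.
#' @export
read_edf_header <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  con <- file(path, open = "rb")
  on.exit(close(con))
  fsize <- file.size(path)
  if (fsize < 256) format_error(sprintf("%s: too short for an EDF header", path))

  f <- list()
  for (nm in names(EDF_FIXED_FIELDS)) {
    f[[nm]] <- read_edf_ascii(con, EDF_FIXED_FIELDS[[nm]])
  }
  if (f$version != "0") {
    format_error(sprintf("%s: EDF version field is '%s', expected '0'", path, f$version))
  }
  ns <- as.integer(edf_header_num(f$n_signals, "n_signals"))
  header_bytes <- as.integer(edf_header_num(f$header_bytes, "header_bytes"))
  if (header_bytes != 256L * (ns + 1L)) {
    format_error(sprintf(
      "%s: header_bytes %d inconsistent with %d signal(s) (expected %d)",
      path, header_bytes, ns, 256L * (ns + 1L)))
  }
  s <- list()
  for (nm in names(EDF_SIGNAL_FIELDS)) {
    s[[nm]] <- read_edf_ascii(con, EDF_SIGNAL_FIELDS[[nm]], ns)
  }
  for (nm in c("physical_min", "physical_max", "digital_min", "digital_max",
               "samples_per_record")) {
    s[[nm]] <- edf_header_num(s[[nm]], nm)
  }
  n_records <- edf_header_num(f$n_records, "n_records")
  record_duration <- edf_header_num(f$record_duration, "record_duration")
  sfreq <- if (record_duration > 0) s$samples_per_record[1] / record_duration else NA_real_

  c(f[c("version", "patient_id", "recording_id", "start_date", "start_time")],
    list(header_bytes = header_bytes, n_records = n_records,
         record_duration = record_duration, n_signals = ns,
         label = s$label, transducer = s$transducer,
         physical_dimension = s$physical_dimension,
         physical_min = s$physical_min, physical_max = s$physical_max,
         digital_min = s$digital_min, digital_max = s$digital_max,
         prefiltering = s$prefiltering,
         samples_per_record = as.integer(s$samples_per_record),
         sfreq = sfreq,
         n_samples = as.integer(n_records * s$samples_per_record[1])))
}

#' Read an EDF file into a recording
#'
#' Returns physical-valued samples via the per-signal affine calibration;
#' channel names come from the signal labels. Digital samples outside the
#' declared digital range are clamped with a warning. A write/read round
#' trip reproduces every sample to within one quantization step
#' `(physical_max - physical_min) / (digital_max - digital_min)` per channel.
#'
#' @param path EDF file.
#' @return An `eeg_recording` (with no events: continuous EDF carries none).
#' @export
read_edf <- function(path) {
  h <- read_edf_header(path)
  ns <- h$n_signals
  spr <- h$samples_per_record
  if (ns > 1 && length(unique(spr)) != 1) {
    format_error(sprintf("%s: per-signal sampling rates differ; unsupported", path))
  }
  if (h$record_duration <= 0) {
    format_error(sprintf("%s: non-positive record duration", path))
  }
  n_rec <- as.integer(h$n_records)
  expected <- h$header_bytes + n_rec * sum(spr) * 2
  fsize <- file.size(path)
  if (fsize < expected) {
    format_error(sprintf(
      "%s: truncated payload: %d bytes on disk, %d expected (short by %d at offset %d)",
      path, fsize, expected, expected - fsize, fsize))
  }
  con <- file(path, open = "rb")
  on.exit(close(con))
  seek(con, h$header_bytes)
  vec <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")

  annot <- h$label == "EDF Annotations"
  if (any(annot)) {
    warning("EDF+ annotations signal present; skipped (events belong in events.tsv)")
  }
  arr <- array(vec, dim = c(spr[1], ns, n_rec))
  keep <- which(!annot)
  data <- matrix(0, length(keep), n_rec * spr[1])
  for (j in seq_along(keep)) {
    i <- keep[j]
    d <- as.vector(arr[, i, ])
    out_of_range <- d < h$digital_min[i] | d > h$digital_max[i]
    if (any(out_of_range)) {
      warning(sprintf("channel '%s': %d sample(s) outside the digital range; clamped",
                      h$label[i], sum(out_of_range)))
      d <- pmin(pmax(d, h$digital_min[i]), h$digital_max[i])
    }
    data[j, ] <- digital_to_physical(d, h$physical_min[i], h$physical_max[i],
                                     h$digital_min[i], h$digital_max[i])
  }
  units <- h$physical_dimension[keep]
  units[units %in% c("", "uV")] <- "µV"
  new_recording(data, sfreq = spr[1] / h$record_duration,
                channel_names = h$label[keep],
                channel_units = units)
}
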