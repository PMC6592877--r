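# BrainVision Core Data Format codec: a triplet of .vhdr (INI-style text
# header), .vmrk (INI-style markers), and .eeg (raw little-endian binary,
# multiplexed sample order). Only BINARY/MULTIPLEXED payloads in INT_16 or
# IEEE_FLOAT_32 encoding are supported; VECTORIZED and ASCII are rejected.

BV_BINARY_FORMATS <- c("IEEE_FLOAT_32", "INT_16")
BV_HEADER_MAGIC <- "BrainVision Data Exchange Header File Version 1.0"
BV_MARKER_MAGIC <- "BrainVision Data Exchange Marker File Version 1.0"

#' Parse INI-style text into a section map
#'
#' The BrainVision header and marker files use the Microsoft Windows INI
#' layout: `[Section]` headers followed by `key=value` lines; `;` lines are
#' comments. A duplicated key within one section keeps the last value with a
#' warning; a key before any section header is a format error.
#'
#' @param text Character vector of lines, or a single string with embedded
#'   newlines (LF or CRLF).
#' @return Named list of sections, each a named character vector of values.
#'   Leading non-section lines that are not `key=value` (the format's magic
#'   preamble) are returned in `attr(, "preamble")`.
#' @export
parse_ini <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\r?\n"))
  sections <- list()
  preamble <- character(0)
  current <- NULL
  for (ln in lines) {
    ln <- sub("\r$", "", ln)
    if (grepl("^\\s*$", ln) || grepl("^\\s*;", ln)) next
    m <- regmatches(ln, regexec("^\\[(.+)\\]\\s*$", ln))[[1]]
    if (length(m) == 2) {
      current <- m[2]
      if (is.null(sections[[current]])) sections[[current]] <- character(0)
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq == -1) {
      if (is.null(current)) {
        preamble <- c(preamble, ln)
        next
      }
      format_error(sprintf("INI line is neither section, comment nor key=value: '%s'", ln))
    }
    if (is.null(current)) {
      format_error(sprintf("key=value line before any [section] header: '%s'", ln))
    }
    key <- trimws(substr(ln, 1, eq - 1))
    val <- substr(ln, eq + 1, nchar(ln))
    if (key %in% names(sections[[current]])) {
      warning(sprintf("duplicate key '%s' in section [%s]; last value wins", key, current))
    }
    sections[[current]][[key]] <- val
  }
  attr(sections, "preamble") <- preamble
  sections
}

read_ini_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) {
    txt <- rawToChar(raw)
    Encoding(txt) <- "latin1"
    txt <- enc2utf8(txt)
  }
  parse_ini(txt)
}

ini_get <- function(sections, section, key, path, default = NULL) {
  v <- sections[[section]][[key]]
  if (is.null(v)) {
    if (!is.null(default)) return(default)
    format_error(sprintf("%s: missing %s/[%s] entry '%s'", path, "", section, key))
  }
  v
}

# escape/unescape commas in channel names per the format's convention
bv_escape <- function(s) gsub(",", "\\\\1", s)
bv_unescape <- function(s) gsub("\\\\1", ",", s)

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg` with mutually
#' consistent cross-references. The payload is multiplexed (all channels of
#' sample 1, then sample 2, ...), little-endian. With the default
#' `IEEE_FLOAT_32` encoding, physical values are stored verbatim at single
#' precision with per-channel resolution 1; with `INT_16`, samples are
#' stored as `round(x / resolution)` with resolution `max|x| / 32767` per
#' channel (1 for an all-zero channel). Events become markers of type
#' `Stimulus` at 1-based sample position `round(onset * sfreq) + 1`; marker 1
#' is the conventional `New Segment` start marker.
#'
#' @param r An [new_recording()] object.
#' @param basepath Output path without extension.
#' @param binary_format `"IEEE_FLOAT_32"` (default) or `"INT_16"`.
#' @param resolution Optional per-channel resolution overriding the INT_16
#'   default; a quantized value outside the 16-bit range raises a range
#'   error.
#' @return Character vector of the three written paths (vhdr, vmrk, eeg).
#' @export
write_brainvision <- function(r, basepath, binary_format = "IEEE_FLOAT_32",
                              resolution = NULL) {
  stopifnot(inherits(r, "eeg_recording"))
  if (!binary_format %in% BV_BINARY_FORMATS) {
    format_error(sprintf("unsupported BinaryFormat '%s' (supported: %s)",
                         binary_format, paste(BV_BINARY_FORMATS, collapse = ", ")))
  }
  if (grepl("\\.(vhdr|vmrk|eeg)$", basepath)) {
    invariant_error("basepath must not carry an extension")
  }
  base <- basename(basepath)
  paths <- paste0(basepath, c(".vhdr", ".vmrk", ".eeg"))
  ns <- n_channels(r)

  if (binary_format == "INT_16") {
    if (is.null(resolution)) {
      m <- apply(abs(r$data), 1, max)
      resolution <- ifelse(m == 0, 1, m / 32767)
    }
    if (length(resolution) == 1) resolution <- rep(resolution, ns)
    dig <- round(sweep(r$data, 1, resolution, "/"))
    if (any(dig < -32768 | dig > 32767)) {
      range_error("INT_16 quantization overflows the 16-bit range; increase resolution")
    }
  } else {
    resolution <- rep(1, ns)
  }

  sampling_interval <- 1e6 / r$sfreq
  vhdr <- c(
    BV_HEADER_MAGIC,
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", ns),
    paste0("SamplingInterval=", sprintf("%.15g", sampling_interval)),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "",
    "[Channel Infos]",
    "; Ch<index>=<name>,<reference>,<resolution in unit>,<unit>",
    sprintf("Ch%d=%s,,%s,%s", seq_len(ns), bv_escape(r$channel_names),
            sprintf("%.15g", resolution), r$channel_units)
  )
  write_lines_lf(vhdr, paths[1])

  ev <- r$events
  vmrk <- c(
    BV_MARKER_MAGIC,
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "; Mk<index>=<type>,<description>,<position in data points>,<points>,<channel (0 = all)>",
    "Mk1=New Segment,,1,1,0",
    if (nrow(ev) > 0) {
      sprintf("Mk%d=Stimulus,%s,%d,%d,0",
              seq_len(nrow(ev)) + 1L,
              bv_escape(ev$description),
              as.integer(round(ev$onset * r$sfreq)) + 1L,
              as.integer(round(ev$duration * r$sfreq)))
    }
  )
  write_lines_lf(vmrk, paths[2])

  con <- file(paths[3], open = "wb")
  on.exit(close(con))
  if (binary_format == "IEEE_FLOAT_32") {
    # column-major over a channels x samples matrix IS multiplexed order
    writeBin(as.vector(r$data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  paths
}

#' Read a BrainVision triplet into a recording
#'
#' Resolves the `.vmrk` and `.eeg` siblings referenced by the header,
#' decodes the multiplexed payload (`INT_16` samples are scaled by the
#' per-channel resolution; `IEEE_FLOAT_32` is read verbatim, so a write/read
#' round trip is exact at single precision), and maps `Stimulus` markers
#' back to events with `onset = (position - 1) / sfreq`.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return An `eeg_recording`.
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) io_error(sprintf("no such file: %s", vhdr_path))
  hdr <- read_ini_file(vhdr_path)
  dirn <- dirname(vhdr_path)

  fmt <- ini_get(hdr, "Common Infos", "DataFormat", vhdr_path, "BINARY")
  if (fmt != "BINARY") {
    format_error(sprintf("%s: DataFormat '%s' unsupported (BINARY only)", vhdr_path, fmt))
  }
  orient <- ini_get(hdr, "Common Infos", "DataOrientation", vhdr_path, "MULTIPLEXED")
  if (orient != "MULTIPLEXED") {
    format_error(sprintf("%s: DataOrientation '%s' unsupported (MULTIPLEXED only)",
                         vhdr_path, orient))
  }
  bfmt <- ini_get(hdr, "Binary Infos", "BinaryFormat", vhdr_path)
  if (!bfmt %in% BV_BINARY_FORMATS) {
    format_error(sprintf("%s: BinaryFormat '%s' unsupported (supported: %s)",
                         vhdr_path, bfmt, paste(BV_BINARY_FORMATS, collapse = ", ")))
  }
  ns <- as.integer(ini_get(hdr, "Common Infos", "NumberOfChannels", vhdr_path))
  si <- as.numeric(ini_get(hdr, "Common Infos", "SamplingInterval", vhdr_path))
  if (is.na(ns) || is.na(si) || ns < 1 || si <= 0) {
    format_error(sprintf("%s: invalid NumberOfChannels/SamplingInterval", vhdr_path))
  }
  sfreq <- 1e6 / si

  ch <- hdr[["Channel Infos"]]
  ch <- ch[grepl("^Ch[0-9]+$", names(ch))]
  ch <- ch[order(as.integer(sub("^Ch", "", names(ch))))]
  if (length(ch) != ns) {
    format_error(sprintf("%s: NumberOfChannels=%d but %d Channel Infos entries",
                         vhdr_path, ns, length(ch)))
  }
  parts <- strsplit(unname(ch), ",", fixed = TRUE)
  ch_names <- bv_unescape(vapply(parts, function(p) p[1], ""))
  ch_res <- vapply(parts, function(p) {
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1
  }, 0)
  ch_units <- vapply(parts, function(p) if (length(p) >= 4) p[4] else "µV", "")
  ch_units[is.na(ch_units) | ch_units == ""] <- "µV"

  data_file <- file.path(dirn, ini_get(hdr, "Common Infos", "DataFile", vhdr_path))
  if (!file.exists(data_file)) {
    format_error(sprintf("%s: referenced data file '%s' not found", vhdr_path, data_file))
  }
  marker_file <- hdr[["Common Infos"]][["MarkerFile"]]

  fsize <- file.size(data_file)
  bytes_per <- if (bfmt == "IEEE_FLOAT_32") 4L else 2L
  if (fsize %% (bytes_per * ns) != 0) {
    format_error(sprintf("%s: payload size %d not a multiple of %d channels x %d bytes",
                         data_file, fsize, ns, bytes_per))
  }
  nsamp <- as.integer(fsize / (bytes_per * ns))
  con <- file(data_file, open = "rb")
  on.exit(close(con))
  if (bfmt == "IEEE_FLOAT_32") {
    vec <- readBin(con, "numeric", n = ns * nsamp, size = 4L, endian = "little")
    data <- matrix(vec, nrow = ns)
  } else {
    vec <- readBin(con, "integer", n = ns * nsamp, size = 2L, signed = TRUE,
                   endian = "little")
    data <- matrix(vec, nrow = ns) * ch_res
  }

  events <- data.frame(onset = numeric(0), duration = numeric(0),
                       description = character(0), stringsAsFactors = FALSE)
  if (!is.null(marker_file)) {
    marker_path <- file.path(dirn, marker_file)
    if (!file.exists(marker_path)) {
      format_error(sprintf("%s: referenced marker file '%s' not found",
                           vhdr_path, marker_path))
    }
    mrk <- read_ini_file(marker_path)[["Marker Infos"]]
    mrk <- mrk[grepl("^Mk[0-9]+$", names(mrk))]
    mrk <- mrk[order(as.integer(sub("^Mk", "", names(mrk))))]
    mp <- strsplit(unname(mrk), ",", fixed = TRUE)
    type <- vapply(mp, function(p) p[1], "")
    stim <- type == "Stimulus"
    if (any(stim)) {
      pos <- vapply(mp[stim], function(p) as.numeric(p[3]), 0)
      pts <- vapply(mp[stim], function(p) if (length(p) >= 4) as.numeric(p[4]) else 0, 0)
      events <- data.frame(
        onset = (pos - 1) / sfreq,
        duration = pts / sfreq,
        description = bv_unescape(vapply(mp[stim], function(p) p[2], "")),
        stringsAsFactors = FALSE)
    }
  }

  new_recording(data, sfreq = sfreq, channel_names = ch_names,
                channel_units = ch_units, events = events)
}
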