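# BrainVision triplet (.vhdr/.vmrk/.eeg) reader and writer.
# Two binary dialects are supported: multiplexed 16-bit signed integers with a
# per-channel resolution, and multiplexed IEEE 32-bit floats. The writer exists
# mainly to produce fixtures and simulator output.

#' Default mapping from marker descriptions to event-log kinds
#'
#' The package's own writer encodes events as `"<kind>:<message_id>"` in the
#' marker description. Recordings from other sources use arbitrary marker
#' strings, so [read_brainvision()] takes a mapping: either a function
#' `description -> list(kind, message_id)` (return `NULL` to drop a marker) or
#' a named character vector `c("S  1" = "msg_first", ...)`.
#'
#' @param description marker description string.
#' @return list with `kind` and `message_id`, or `NULL`.
#' @export
default_marker_map <- function(description) {
  parts <- strsplit(description, ":", fixed = TRUE)[[1]]
  if (!(parts[1] %in% EVENT_KINDS)) return(NULL)
  id <- if (length(parts) > 1) suppressWarnings(as.integer(parts[2])) else NA_integer_
  list(kind = parts[1], message_id = id)
}

#' Write a recording and event log as a BrainVision triplet
#'
#' @param rec an [eeg_recording()].
#' @param log an [event_log()] (may be empty).
#' @param base_path path without extension; `.vhdr`, `.vmrk`, `.eeg` are added.
#' @param binary_format `"int16"` (with `resolution` uV/bit) or `"float32"`.
#' @param resolution per-channel resolution in uV per bit (int16 only).
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, log = event_log(), base_path,
                              binary_format = c("int16", "float32"),
                              resolution = 0.1) {
  binary_format <- match.arg(binary_format)
  stem <- basename(base_path)
  vhdr <- paste0(base_path, ".vhdr")
  vmrk <- paste0(base_path, ".vmrk")
  eeg <- paste0(base_path, ".eeg")
  nc <- n_channels(rec)

  fmt_name <- if (binary_format == "int16") "INT_16" else "IEEE_FLOAT_32"
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", stem),
    sprintf("MarkerFile=%s.vmrk", stem),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nc),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
    "[Binary Infos]",
    sprintf("BinaryFormat=%s", fmt_name),
    "[Channel Infos]",
    vapply(seq_len(nc), function(i) {
      res <- if (binary_format == "int16") sprintf("%.10g", resolution) else "1"
      sprintf("Ch%d=%s,%s,%s,µV", i, rec$channel_labels[i],
              rec$reference_label, res)
    }, character(1))
  )
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", stem),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (nrow(log) > 0) {
    for (i in seq_len(nrow(log))) {
      pos <- floor(log$time_s[i] * rec$fs) + 1
      desc <- if (is.na(log$message_id[i])) log$kind[i] else
        sprintf("%s:%d", log$kind[i], log$message_id[i])
      typ <- if (log$kind[i] == "response") "Response" else "Stimulus"
      mk <- c(mk, sprintf("Mk%d=%s,%s,%d,1,0", i + 1, typ, desc, pos))
    }
  }
  writeLines(mk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  x <- rec$data  # channels x samples; multiplexed = column-major of this matrix
  if (binary_format == "int16") {
    q <- round(x / resolution)
    assert_that(max(abs(q)) <= 32767,
                "signal exceeds int16 range at resolution %g uV/bit", resolution)
    writeBin(as.integer(q), con, size = 2, endian = "little")
  } else {
    writeBin(as.vector(x), con, size = 4, endian = "little")
  }
  invisible(vhdr)
}

parse_vhdr_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  sec <- ""
  out <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) { sec <- gsub("^\\[|\\]$", "", ln); next }
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) == 3) out[[sec]][[trimws(m[2])]] <- m[3]
  }
  out
}

#' Read a BrainVision triplet
#'
#' Supports multiplexed INT_16 (per-channel resolution applied, output in uV)
#' and IEEE_FLOAT_32 data. Marker sample positions are converted to seconds
#' from recording start; descriptions are mapped to event kinds through
#' `marker_map` and unmapped markers are dropped.
#'
#' @param header_path path to the `.vhdr` file.
#' @param marker_map mapping from marker description to event kind; see
#'   [default_marker_map()].
#' @return list with elements `recording` ([eeg_recording()]) and
#'   `events` ([event_log()]).
#' @export
read_brainvision <- function(header_path, marker_map = default_marker_map) {
  assert_that(file.exists(header_path), "header file not found: %s", header_path)
  ini <- parse_vhdr_ini(readLines(header_path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  dir <- dirname(header_path)
  data_file <- file.path(dir, ci$DataFile)
  marker_file <- file.path(dir, ci$MarkerFile)
  assert_that(file.exists(data_file), "data file not found: %s", data_file)
  assert_that(file.exists(marker_file), "marker file not found: %s", marker_file)
  assert_that(identical(ci$DataOrientation %||% "MULTIPLEXED", "MULTIPLEXED"),
              "unsupported data orientation: %s", ci$DataOrientation)
  nc <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  fmt <- bi$BinaryFormat
  assert_that(fmt %in% c("INT_16", "IEEE_FLOAT_32"),
              "unsupported binary format: %s", fmt)

  chinfo <- ini[["Channel Infos"]]
  labels <- character(nc); res <- rep(1, nc); ref <- "FCz"
  for (i in seq_len(nc)) {
    parts <- strsplit(chinfo[[sprintf("Ch%d", i)]], ",")[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 2 && nzchar(parts[2])) ref <- parts[2]
    if (length(parts) >= 3 && nzchar(parts[3])) res[i] <- as.numeric(parts[3])
  }

  sz <- file.info(data_file)$size
  bytes <- if (fmt == "INT_16") 2L else 4L
  ns <- as.integer(sz / (bytes * nc))
  con <- file(data_file, "rb")
  on.exit(close(con))
  raw_vals <- if (fmt == "INT_16") {
    readBin(con, integer(), n = nc * ns, size = 2, endian = "little")
  } else {
    readBin(con, numeric(), n = nc * ns, size = 4, endian = "little")
  }
  x <- matrix(as.numeric(raw_vals), nrow = nc)
  if (fmt == "INT_16") x <- x * res  # res recycles over the channel dimension

  mapper <- if (is.function(marker_map)) marker_map else {
    tab <- marker_map
    function(d) if (d %in% names(tab)) list(kind = unname(tab[[d]]), message_id = NA_integer_) else NULL
  }
  mrk <- parse_vhdr_ini(readLines(marker_file, warn = FALSE))[["Marker Infos"]]
  ev <- list()
  for (nm in names(mrk)) {
    parts <- strsplit(mrk[[nm]], ",")[[1]]
    if (length(parts) < 3 || parts[1] == "New Segment") next
    mapped <- mapper(parts[2])
    if (is.null(mapped)) next
    pos <- as.numeric(parts[3])
    assert_that(pos >= 1 && pos <= ns,
                "marker '%s' at sample %g beyond data length %d", parts[2], pos, ns)
    ev[[length(ev) + 1]] <- data.frame(
      time_s = (pos - 1) / fs, kind = mapped$kind,
      message_id = mapped$message_id %||% NA_integer_,
      stringsAsFactors = FALSE)
  }
  events <- if (length(ev) > 0) as_event_log(do.call(rbind, ev)) else event_log()
  list(recording = eeg_recording(x, fs, labels, ref), events = events)
}
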