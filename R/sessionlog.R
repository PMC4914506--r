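# JSON-lines session log: one header line with an explicit schema version,
# then one JSON object per event. CSV export for analysis tools.

SESSION_LOG_SCHEMA <- "p300loop/events"
SESSION_LOG_VERSION <- 1L

#' Write / read a session event log as JSON lines
#'
#' The file starts with a schema/version header line; each following line is
#' one event object. `read_session_log(write_session_log(log))` is the
#' identity for any valid log.
#'
#' @param log an [event_log()].
#' @param path file path.
#' @return `write_session_log`: the path, invisibly. `read_session_log`: an
#'   [event_log()].
#' @export
write_session_log <- function(log, path) {
  validate_event_log(log)
  header <- jsonlite::toJSON(list(schema = SESSION_LOG_SCHEMA,
                                  version = SESSION_LOG_VERSION),
                             auto_unbox = TRUE)
  lines <- character(nrow(log))
  for (i in seq_len(nrow(log))) {
    rec <- as.list(as.data.frame(log)[i, , drop = FALSE])
    rec <- rec[!vapply(rec, function(v) length(v) == 1 && is.na(v), logical(1))]
    # I(17) significant digits: doubles survive the text round trip exactly
    lines[i] <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  assert_that(file.exists(path), "session log not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  assert_that(length(lines) >= 1, "empty file: %s", path)
  header <- jsonlite::fromJSON(lines[1])
  assert_that(identical(header$schema, SESSION_LOG_SCHEMA),
              "not a session log (schema '%s')", header$schema %||% "?")
  assert_that(identical(as.integer(header$version), SESSION_LOG_VERSION),
              "unsupported session log version %s", header$version)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(event_log())
  rows <- vector("list", length(body))
  last_t <- -Inf
  for (i in seq_along(body)) {
    rec <- tryCatch(jsonlite::fromJSON(body[i]),
                    error = function(e) stopf("line %d: malformed JSON", i + 1))
    assert_that(!is.null(rec$time_s) && !is.null(rec$kind),
                "line %d: missing time_s or kind", i + 1)
    assert_that(rec$kind %in% EVENT_KINDS, "line %d: unknown kind '%s'",
                i + 1, rec$kind)
    assert_that(rec$time_s >= last_t, "line %d: out-of-order time %.6g",
                i + 1, rec$time_s)
    last_t <- rec$time_s
    rows[[i]] <- data.frame(
      time_s = as.numeric(rec$time_s), kind = rec$kind,
      message_id = as.integer(rec$message_id %||% NA),
      robot = as.integer(rec$robot %||% NA),
      task_type = as.character(rec$task_type %||% NA),
      queued_at = as.numeric(rec$queued_at %||% NA),
      stringsAsFactors = FALSE)
  }
  as_event_log(do.call(rbind, rows))
}

#' Export a session log as CSV
#'
#' @param log an [event_log()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_session_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, na = "")
  invisible(path)
}
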