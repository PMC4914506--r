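#' Event kinds understood by the session log
#'
#' Marker vocabulary of an interaction session: first presentation of a task
#' message, repeated presentation, end of a presentation, operator response,
#' robot command, and session delimiters.
#' @export
EVENT_KINDS <- c("msg_first", "msg_repeat", "msg_offset", "response",
                 "robot_command", "session_start", "session_end")

#' Task types carried by message events
#' @export
TASK_TYPES <- c("send_message", "go_to_landmark", "recharge")

#' Timestamped typed event log
#'
#' Ordered log of session events. Times are seconds from recording start
#' (float); epoch windows elsewhere in the package are half-open
#' `[t_on, t_off)`. `queued_at` is only set for `msg_repeat` events and holds
#' the time the repetition was appended to the message queue (the response
#' deadline of the unanswered presentation); the event's own `time_s` is its
#' presentation onset.
#'
#' @param time_s numeric, non-decreasing times in seconds.
#' @param kind character, each in [EVENT_KINDS].
#' @param message_id integer id (NA for session markers / robot commands).
#' @param robot robot identifier (metadata).
#' @param task_type one of [TASK_TYPES] (metadata).
#' @param queued_at queue-insertion time for repeats, else NA.
#' @return data.frame of class `event_log`.
#' @export
event_log <- function(time_s = numeric(), kind = character(),
                      message_id = NA_integer_, robot = NA_integer_,
                      task_type = NA_character_, queued_at = NA_real_) {
  n <- length(time_s)
  df <- data.frame(time_s = as.numeric(time_s),
                   kind = rep_len(as.character(kind), n),
                   message_id = rep_len(as.integer(message_id), n),
                   robot = rep_len(as.integer(robot), n),
                   task_type = rep_len(as.character(task_type), n),
                   queued_at = rep_len(as.numeric(queued_at), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("event_log", "data.frame")
  validate_event_log(df)
  df
}

#' Validate an event log
#'
#' Checks the `event_log` invariants: non-decreasing times, kinds restricted
#' to [EVENT_KINDS], and every `msg_offset` preceded by an onset with the
#' same message id.
#'
#' @param log an [event_log()].
#' @return the log, invisibly; errors on violation.
#' @export
validate_event_log <- function(log) {
  if (nrow(log) == 0) return(invisible(log))
  bad <- setdiff(unique(log$kind), EVENT_KINDS)
  assert_that(length(bad) == 0, "unknown event kind(s): %s", paste(bad, collapse = ", "))
  assert_that(!is.unsorted(log$time_s), "event times must be non-decreasing")
  off <- which(log$kind == "msg_offset")
  for (i in off) {
    on <- which(log$kind %in% c("msg_first", "msg_repeat") &
                  log$message_id == log$message_id[i] &
                  log$time_s <= log$time_s[i])
    assert_that(length(on) > 0,
                "msg_offset for message %d at %.3f s has no earlier onset",
                log$message_id[i], log$time_s[i])
  }
  invisible(log)
}

as_event_log <- function(df) {
  cols <- c("time_s", "kind", "message_id", "robot", "task_type", "queued_at")
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
  df <- df[cols]
  df$time_s <- as.numeric(df$time_s)
  df$message_id <- as.integer(df$message_id)
  df$robot <- as.integer(df$robot)
  df$queued_at <- as.numeric(df$queued_at)
  df <- df[order(df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_log", "data.frame")
  validate_event_log(df)
  df
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d events", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(" over %.1f s; %d first messages, %d repeats, %d responses",
                diff(range(x$time_s)), sum(x$kind == "msg_first"),
                sum(x$kind == "msg_repeat"), sum(x$kind == "response")))
  }
  cat("\n")
  invisible(x)
}

#' Response latency per first task message
#'
#' For every `msg_first` event, the latency (s) of the first `response` event
#' with the same message id at or after the presentation onset, or `NA` if the
#' message was never answered. Repetitions are not rows here: a response after
#' a repeat still resolves the original message and its latency is measured
#' from the first presentation.
#'
#' @param log an [event_log()].
#' @return data.frame with columns `message_id`, `onset`, `latency`.
#' @export
response_latencies <- function(log) {
  firsts <- log[log$kind == "msg_first", , drop = FALSE]
  resp <- log[log$kind == "response", , drop = FALSE]
  lat <- vapply(seq_len(nrow(firsts)), function(i) {
    r <- resp$time_s[resp$message_id == firsts$message_id[i] &
                       resp$time_s >= firsts$time_s[i]]
    if (length(r) == 0) NA_real_ else min(r) - firsts$time_s[i]
  }, numeric(1))
  data.frame(message_id = firsts$message_id, onset = firsts$time_s,
             latency = lat)
}
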