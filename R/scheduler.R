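# Discrete-event message scheduler. Presents queued task messages whenever
# the current ISI has elapsed since the previous presentation offset
# (offset-to-onset convention), enforces the response timeout by re-queueing
# unanswered messages as repeats with elevated priority, and - in adaptive
# mode - feeds each first-message detection outcome to the ISI controller.

#' Simulate a message-scheduling session (events only, no EEG)
#'
#' Runs the scheduler/operator/controller automaton and returns the event
#' log, per-message ground truth and the controller trace. EEG synthesis is
#' layered on top by [simulate_session()].
#'
#' Scheduling rules: the head-of-queue message is presented when the current
#' ISI has elapsed since the previous presentation offset; presentations last
#' `cfg$presentation_s` (1.1 s); a message unanswered
#' `cfg$response_timeout` (13 s) after its presentation onset is re-appended
#' to the FIFO queue as a `msg_repeat` with elevated priority (repeats are
#' dequeued before newer first messages; FIFO within each priority level).
#' A message is repeated at most `max_repeats` times before it counts as
#' missed for good. The run ends once `n_messages` first messages have been
#' presented and the last message's fate is settled.
#'
#' The simulated operator answers each presentation of a still-unanswered
#' message with probability `1 - p_miss(dt)` at a sampled latency, where `dt`
#' is the time since the previous first-message onset (the engagement proxy).
#' A recognized first message evokes an ERP with amplitude multiplier
#' `g(dt)`; a missed one evokes none (multiplier 0).
#'
#' @param op an [operator_model()].
#' @param cfg a [pipeline_config()].
#' @param mode `"fixed"` (nominal ISI + uniform jitter) or `"adaptive"`
#'   (controller-driven, no jitter).
#' @param nominal nominal ISI in seconds (fixed mode).
#' @param jitter jitter half-range in seconds (fixed mode).
#' @param n_messages number of first task messages in the run (study: 30).
#' @param seed RNG seed for the whole session.
#' @param engagement_gain amplitude multiplier function `g(dt)`; defaults to
#'   the [simulation_config()] default.
#' @param decide detection callback `function(msg_index, onset, amplitude)`
#'   returning TRUE/FALSE, used in adaptive mode. Required there.
#' @param controller an [isi_controller()]; defaults to `cfg` values.
#' @param t_start onset of the first presentation, s.
#' @param max_repeats repetition cap per message.
#' @return list with `events` ([event_log()]), `truth` (per first message:
#'   onset, dt, amplitude multiplier, recognized flag, response latency,
#'   repeat count), `trace` (per first message: ISI used, outcome, ISI after
#'   update) and the final `controller`.
#' @export
simulate_schedule <- function(op, cfg = pipeline_config(),
                              mode = c("fixed", "adaptive"),
                              nominal = cfg$isi_preset, jitter = cfg$jitter_s,
                              n_messages = 30, seed = 1L,
                              engagement_gain = function(dt) clip(dt / 20, 0.3, 1),
                              decide = NULL, controller = NULL,
                              t_start = 30, max_repeats = 2) {
  mode <- match.arg(mode)
  if (mode == "adaptive") {
    assert_that(is.function(decide), "adaptive mode needs a `decide` callback")
    if (is.null(controller))
      controller <- isi_controller(cfg$isi_preset, cfg$isi_min, cfg$isi_max,
                                   cfg$isi_step, cfg$streak_len)
  }
  with_seed(seed, {
    pres_s <- cfg$presentation_s
    timeout <- cfg$response_timeout

    msg_meta <- data.frame(message_id = seq_len(n_messages),
                           robot = sample.int(4, n_messages, replace = TRUE),
                           task_type = sample(TASK_TYPES, n_messages, replace = TRUE))
    response_time <- rep(NA_real_, n_messages)
    rep_count <- integer(n_messages)
    missed_final <- logical(n_messages)

    queue <- list()            # repeats ready for presentation
    pending <- list()          # repeats scheduled to enter the queue later
    ev <- list(); truth <- list(); trace <- list()
    t_last_offset <- NA_real_
    prev_first <- -Inf
    n_first <- 0L

    emit <- function(time_s, kind, id, queued_at = NA_real_) {
      ev[[length(ev) + 1L]] <<- data.frame(
        time_s = time_s, kind = kind, message_id = id,
        robot = if (is.na(id)) NA_integer_ else msg_meta$robot[id],
        task_type = if (is.na(id)) NA_character_ else msg_meta$task_type[id],
        queued_at = queued_at, stringsAsFactors = FALSE)
    }
    emit(0, "session_start", NA_integer_)

    resolved_by <- function(id, t) !is.na(response_time[id]) && response_time[id] <= t

    repeat {
      # next allowed presentation time under the current ISI
      if (is.na(t_last_offset)) {
        tp <- t_start
        isi_used <- NA_real_
      } else {
        isi_used <- if (mode == "fixed") nominal + stats::runif(1, -jitter, jitter)
                    else controller$isi
        tp <- t_last_offset + isi_used
      }
      # repeats whose enqueue time has passed join the FIFO queue
      promote <- function(tp) {
        keep <- logical(length(pending))
        for (i in seq_along(pending)) {
          if (pending[[i]]$time <= tp) queue[[length(queue) + 1L]] <<- pending[[i]]
          else keep[i] <- TRUE
        }
        pending <<- pending[keep]
      }
      promote(tp)
      # drop queued repeats of messages answered in the meantime
      queue <- Filter(function(q) !resolved_by(q$message_id, tp), queue)

      if (length(queue) > 0) {
        item <- queue[[1]]; queue <- queue[-1]
        kind <- "msg_repeat"; id <- item$message_id; queued_at <- item$time
      } else if (n_first < n_messages) {
        n_first <- n_first + 1L
        kind <- "msg_first"; id <- n_first; queued_at <- NA_real_
      } else if (length(pending) > 0) {
        # nothing ready: idle until the earliest scheduled repeat
        t_next <- min(vapply(pending, function(p) p$time, numeric(1)))
        tp <- max(tp, t_next)
        promote(tp)
        queue <- Filter(function(q) !resolved_by(q$message_id, tp), queue)
        if (length(queue) == 0) break
        item <- queue[[1]]; queue <- queue[-1]
        kind <- "msg_repeat"; id <- item$message_id; queued_at <- item$time
      } else break

      emit(tp, kind, id, queued_at)
      emit(tp + pres_s, "msg_offset", id)

      amplitude <- NA_real_
      if (kind == "msg_first") {
        dt <- tp - prev_first
        prev_first <- tp
        recognized <- stats::runif(1) >= op$p_miss(dt)
        amplitude <- if (recognized) engagement_gain(dt) else 0
        if (recognized && is.na(response_time[id]))
          response_time[id] <- tp + op$rt_sampler(1)
        truth[[length(truth) + 1L]] <- data.frame(
          message_id = id, onset = tp, dt = dt, amplitude = amplitude,
          recognized = recognized)
      } else if (is.na(response_time[id])) {
        dt <- tp - prev_first
        if (stats::runif(1) >= op$p_miss(dt))
          response_time[id] <- tp + op$rt_sampler(1)
      }

      # timeout: unanswered within `timeout` s of this onset -> re-queue
      if ((is.na(response_time[id]) || response_time[id] > tp + timeout)) {
        if (rep_count[id] < max_repeats) {
          rep_count[id] <- rep_count[id] + 1L
          pending[[length(pending) + 1L]] <- list(time = tp + timeout,
                                                  message_id = id)
        } else if (is.na(response_time[id])) {
          missed_final[id] <- TRUE
        }
      }

      if (kind == "msg_first" && mode == "adaptive") {
        detected <- isTRUE(decide(n_first, tp, amplitude))
        controller <- controller_update(controller, detected)
        trace[[length(trace) + 1L]] <- data.frame(
          msg_index = n_first, onset = tp, isi_used = isi_used,
          amplitude = amplitude, detected = detected,
          isi_after = controller$isi)
      } else if (kind == "msg_first") {
        trace[[length(trace) + 1L]] <- data.frame(
          msg_index = n_first, onset = tp, isi_used = isi_used,
          amplitude = amplitude, detected = NA, isi_after = NA_real_)
      }

      t_last_offset <- tp + pres_s
    }

    for (id in seq_len(n_messages))
      if (!is.na(response_time[id])) emit(response_time[id], "response", id)
    t_end <- max(vapply(ev, function(e) e$time_s, numeric(1))) + 1
    emit(t_end, "session_end", NA_integer_)

    truth <- do.call(rbind, truth)
    truth$response_latency <- response_time[truth$message_id] - truth$onset
    truth$n_repeats <- rep_count[truth$message_id]
    list(events = as_event_log(do.call(rbind, ev)),
         truth = truth,
         trace = do.call(rbind, trace),
         controller = if (mode == "adaptive") controller else NULL)
  })
}
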