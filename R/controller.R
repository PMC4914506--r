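#' Closed-loop ISI controller state
#'
#' State of the inter-stimulus-interval adaptation rule: the current ISI, two
#' streak counters (consecutive detected / consecutive not-detected
#' outcomes), the bounds, the step size, and the streak length that triggers
#' an adjustment. Defaults are the study values: preset 25 s, bounds 5-35 s,
#' step 5 s, trigger after two identical outcomes in a row. At most one of
#' the two streak counters is nonzero at any time.
#'
#' @param isi initial ISI in seconds (default: the 25 s preset).
#' @param isi_min,isi_max ISI bounds in seconds.
#' @param step adjustment step in seconds.
#' @param streak_len number of consecutive identical outcomes that triggers
#'   one step.
#' @return list of class `isi_controller`.
#' @export
isi_controller <- function(isi = 25, isi_min = 5, isi_max = 35, step = 5,
                           streak_len = 2) {
  assert_that(isi_min <= isi && isi <= isi_max, "need isi_min <= isi <= isi_max")
  assert_that(step > 0 && streak_len >= 1, "step and streak_len must be positive")
  structure(list(isi = isi, streak_detected = 0L, streak_missed = 0L,
                 isi_min = isi_min, isi_max = isi_max, step = step,
                 streak_len = as.integer(streak_len)),
            class = "isi_controller")
}

#' Update the controller with one detection outcome
#'
#' A detected P300 (operator not engaged: capacity free) increments the
#' detected streak and zeroes the missed streak, and vice versa. When a
#' streak reaches `streak_len` the ISI moves one `step` - down for detected
#' outcomes (messages can come faster), up for not-detected outcomes - clipped
#' to the bounds, and the triggering streak resets to zero so that `2k`
#' consecutive identical outcomes produce `k` steps.
#'
#' @param state an [isi_controller()].
#' @param detected logical detection outcome for the latest first task
#'   message.
#' @return the updated `isi_controller`.
#' @export
controller_update <- function(state, detected) {
  assert_that(is.logical(detected) && length(detected) == 1 && !is.na(detected),
              "`detected` must be TRUE or FALSE")
  if (detected) {
    state$streak_detected <- state$streak_detected + 1L
    state$streak_missed <- 0L
    if (state$streak_detected >= state$streak_len) {
      state$isi <- max(state$isi - state$step, state$isi_min)
      state$streak_detected <- 0L
    }
  } else {
    state$streak_missed <- state$streak_missed + 1L
    state$streak_detected <- 0L
    if (state$streak_missed >= state$streak_len) {
      state$isi <- min(state$isi + state$step, state$isi_max)
      state$streak_missed <- 0L
    }
  }
  state
}

#' @export
print.isi_controller <- function(x, ...) {
  cat(sprintf("<isi_controller> ISI %g s in [%g, %g], step %g, streaks det=%d miss=%d\n",
              x$isi, x$isi_min, x$isi_max, x$step,
              x$streak_detected, x$streak_missed))
  invisible(x)
}

#' Draw the next inter-stimulus interval
#'
#' In fixed mode the nominal ISI plus a uniform jitter draw on
#' `[-jitter, +jitter]`; in adaptive mode the controller's current ISI with
#' no jitter.
#'
#' @param mode `"fixed"` or `"adaptive"`.
#' @param nominal nominal ISI in seconds (fixed mode).
#' @param jitter jitter half-range in seconds (fixed mode; default 5).
#' @param controller an [isi_controller()] (adaptive mode).
#' @return ISI in seconds.
#' @export
next_isi <- function(mode = c("fixed", "adaptive"), nominal = NULL,
                     jitter = 5, controller = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    assert_that(!is.null(nominal), "fixed mode needs a nominal ISI")
    nominal + stats::runif(1, -jitter, jitter)
  } else {
    assert_that(inherits(controller, "isi_controller"),
                "adaptive mode needs an isi_controller")
    controller$isi
  }
}
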