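#' Simulated operator model
#'
#' Response behavior of a simulated operator: a positive reaction-time
#' distribution with a heavy tail (so that late responses beyond the 15 s
#' training cutoff occur) and an engagement-dependent miss probability
#' `p_miss(dt)` where `dt` is the time since the previous first task message
#' (short `dt` = operator still engaged = more likely to miss).
#'
#' @param rt_sampler function `n -> n` positive latencies in seconds.
#'   Default: lognormal with median 4 s and sdlog 0.8 (about 5% of responses
#'   beyond 15 s).
#' @param p_miss function `dt -> probability in [0,1]`, non-increasing in
#'   `dt`. Default `0.02 + 0.28 * exp(-dt / 8)`.
#' @param seed RNG seed used when the operator is simulated standalone.
#' @return list of class `operator_model`.
#' @export
operator_model <- function(rt_sampler = function(n) stats::rlnorm(n, log(4), 0.8),
                           p_miss = function(dt) clip(0.02 + 0.28 * exp(-dt / 8), 0, 1),
                           seed = 1L) {
  assert_that(is.function(rt_sampler) && is.function(p_miss),
              "rt_sampler and p_miss must be functions")
  structure(list(rt_sampler = rt_sampler, p_miss = p_miss,
                 seed = as.integer(seed)),
            class = "operator_model")
}

#' Simulate operator responses to a message schedule
#'
#' Walks the presentations of `schedule` in time order. For every
#' presentation of a not-yet-answered message the operator either misses it
#' (probability `p_miss(dt)`, with `dt` the time since the previous
#' `msg_first` onset) or answers at `onset + latency` with a sampled latency.
#' The first response resolves a message; later presentations of a resolved
#' message draw nothing. Deterministic under the seed.
#'
#' @param op an [operator_model()].
#' @param schedule an [event_log()] containing `msg_first` / `msg_repeat`
#'   events.
#' @param seed RNG seed; defaults to `op$seed`.
#' @return an [event_log()] with `response` events merged in.
#' @export
simulate_operator <- function(op, schedule, seed = op$seed) {
  pres <- schedule[schedule$kind %in% c("msg_first", "msg_repeat"), , drop = FALSE]
  with_seed(seed, {
    answered_at <- list()  # message_id -> response time
    prev_first <- -Inf
    resp <- list()
    for (i in seq_len(nrow(pres))) {
      t <- pres$time_s[i]
      id <- pres$message_id[i]
      if (pres$kind[i] == "msg_first") {
        dt <- t - prev_first
        prev_first <- t
      } else dt <- t - prev_first
      key <- as.character(id)
      already <- !is.null(answered_at[[key]]) && answered_at[[key]] <= t
      if (already) next
      if (stats::runif(1) < op$p_miss(dt)) next
      latency <- op$rt_sampler(1)
      t_resp <- t + latency
      if (is.null(answered_at[[key]]) || t_resp < answered_at[[key]])
        answered_at[[key]] <- t_resp
    }
    for (key in names(answered_at)) {
      resp[[length(resp) + 1]] <- data.frame(
        time_s = answered_at[[key]], kind = "response",
        message_id = as.integer(key), stringsAsFactors = FALSE)
    }
    out <- rbind(as.data.frame(schedule)[names(schedule)],
                 if (length(resp)) {
                   r <- do.call(rbind, resp)
                   r$robot <- NA_integer_; r$task_type <- NA_character_
                   r$queued_at <- NA_real_
                   r[names(schedule)]
                 })
    as_event_log(out)
  })
}
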