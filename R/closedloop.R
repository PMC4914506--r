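# Full synthetic sessions: scheduler + operator + EEG synthesis, with the
# option of running a trained decoder in the loop so that the ISI adapts to
# what the classifier actually detects in the synthesized signal.

#' Oracle decoder for closed-loop experiments
#'
#' Thresholds the true injected ERP amplitude multiplier instead of decoding
#' the EEG: `detected = amplitude >= threshold`. `threshold = -Inf` always
#' detects, `threshold = Inf` never does. Useful for isolating controller
#' behavior from decoding accuracy.
#'
#' @param threshold amplitude-multiplier threshold.
#' @return object of class `oracle_decoder`.
#' @export
oracle_decoder <- function(threshold = 0.5) {
  structure(list(threshold = threshold), class = "oracle_decoder")
}

#' Simulate a complete session with synthetic EEG
#'
#' Generates the interaction session of [simulate_schedule()] and a matching
#' EEG recording: 1/f + white background noise, boxcar artifacts, and one
#' stimulus-locked ERP per recognized first task message with amplitude
#' `erp_amp_uv * g(dt)`. In adaptive mode with a trained
#' [`p300_decoder`][train_decoder] the EEG is synthesized incrementally and
#' each post-message window is classified online, so the ISI trace reflects
#' real single-trial detections; with an [oracle_decoder()] (or in fixed
#' mode) the events are simulated first and the EEG is rendered afterwards,
#' which is bit-identical but cheaper.
#'
#' @param sim a [simulation_config()].
#' @param op an [operator_model()].
#' @param cfg a [pipeline_config()].
#' @param mode `"fixed"` or `"adaptive"`.
#' @param nominal,jitter fixed-mode nominal ISI and jitter (s).
#' @param decoder `NULL` (fixed mode), an [oracle_decoder()], or a trained
#'   `p300_decoder` (adaptive mode).
#' @param n_messages first messages per run (study: 30).
#' @param seed session seed; schedule, noise and artifacts derive their own
#'   streams from it.
#' @param t_start onset of the first presentation, s.
#' @param warmup_s online preprocessing warm-up before each classified
#'   window, s.
#' @return list with `recording`, `events`, `truth`, `trace`, `controller`,
#'   and `artifacts` (injected intervals).
#' @export
simulate_session <- function(sim, op, cfg = pipeline_config(),
                             mode = c("fixed", "adaptive"),
                             nominal = cfg$isi_preset, jitter = cfg$jitter_s,
                             decoder = NULL, n_messages = 30, seed = 1L,
                             t_start = 30, warmup_s = 20) {
  mode <- match.arg(mode)
  if (mode == "adaptive") {
    assert_that(!is.null(decoder),
                "adaptive mode needs a decoder (trained or oracle)")
  }
  online <- mode == "adaptive" && inherits(decoder, "p300_decoder")

  if (!online) {
    decide <- if (mode == "adaptive") {
      function(idx, onset, amplitude) amplitude >= decoder$threshold
    } else NULL
    sess <- simulate_schedule(op, cfg, mode, nominal, jitter, n_messages,
                              seed = seed, engagement_gain = sim$engagement_gain,
                              decide = decide, t_start = t_start)
    dur <- max(sess$events$time_s) + 2
    rec <- generate_noise(sim, dur, seed = seed + 1L)
    art <- inject_artifacts(rec, sim, seed = seed + 2L)
    inj <- inject_erp(art$recording, sess$events, sim,
                      amplitudes = sess$truth$amplitude)
    return(list(recording = inj$recording, events = sess$events,
                truth = sess$truth, trace = sess$trace,
                controller = sess$controller, artifacts = art$intervals))
  }

  # online path: synthesize noise in blocks, inject ERPs as messages appear,
  # classify each completed post-message window from the composed signal
  fs <- sim$fs_raw
  block_s <- 120
  est_dur <- t_start + 3 * n_messages * (cfg$isi_max + cfg$presentation_s) + 60
  buf <- new.env(parent = emptyenv())
  buf$x <- matrix(0, sim$n_channels, 0)
  buf$blocks <- 0L
  buf$artifacts <- list()
  ensure <- function(n_need) {
    while (ncol(buf$x) < n_need) {
      buf$blocks <- buf$blocks + 1L
      blk <- generate_noise(sim, block_s, seed = seed + 100L + buf$blocks)
      blk <- inject_artifacts(blk, sim, seed = seed + 500L + buf$blocks)
      off <- ncol(buf$x) / fs
      if (nrow(blk$intervals) > 0) {
        iv <- blk$intervals
        iv$onset <- iv$onset + off; iv$offset <- iv$offset + off
        buf$artifacts[[length(buf$artifacts) + 1L]] <- iv
      }
      buf$x <- cbind(buf$x, blk$recording$data)
    }
  }
  tmpl <- erp_template(sim, fs)
  pat <- erp_spatial_pattern(sim)
  decide <- function(idx, onset, amplitude) {
    s0 <- floor(onset * fs) + 1
    ensure(s0 + round((cfg$window_s + 1) * fs))
    a <- sim$erp_amp_uv * amplitude
    if (a != 0) {
      idxs <- s0:(s0 + length(tmpl) - 1)
      buf$x[, idxs] <- buf$x[, idxs] + outer(pat, a * tmpl)
    }
    t_from <- max(0, onset - warmup_s)
    sa <- floor(t_from * fs) + 1
    sb <- floor((onset + cfg$window_s) * fs)
    seg <- eeg_recording(buf$x[, sa:sb, drop = FALSE], fs,
                         sim$layout$label, "FCz")
    seg <- dc_remove(seg, cfg$dc_time_constant)
    seg <- decimate_recording(seg, cfg$fs_dec, cfg$anti_alias_cutoff,
                              phase = "causal")
    k0 <- floor((onset - t_from) * cfg$fs_dec) + 1
    win <- seg$data[, k0:(k0 + round(cfg$window_s * cfg$fs_dec) - 1), drop = FALSE]
    classify_epoch(decoder, win)$detected
  }
  sess <- simulate_schedule(op, cfg, "adaptive", n_messages = n_messages,
                            seed = seed, engagement_gain = sim$engagement_gain,
                            decide = decide, t_start = t_start)
  dur <- max(sess$events$time_s) + 2
  ensure(round(dur * fs))
  # render ERPs of messages never classified (none in adaptive mode) is not
  # needed: every first message was injected inside `decide`
  rec <- eeg_recording(buf$x[, seq_len(round(dur * fs)), drop = FALSE],
                       fs, sim$layout$label, "FCz")
  art <- if (length(buf$artifacts)) do.call(rbind, buf$artifacts) else
    data.frame(onset = numeric(), offset = numeric(), channel = integer(),
               sign = numeric())
  list(recording = rec, events = sess$events, truth = sess$truth,
       trace = sess$trace, controller = sess$controller,
       artifacts = art[art$onset < dur, , drop = FALSE])
}

#' Run the closed loop: adaptive-ISI session with online detection
#'
#' Convenience wrapper for [simulate_session()] in adaptive mode. The
#' returned `trace` (ISI per message with its detection outcome) is the
#' closed-loop trajectory of the run.
#'
#' @inheritParams simulate_session
#' @return see [simulate_session()].
#' @export
run_closed_loop <- function(sim, op, cfg = pipeline_config(), decoder,
                            n_messages = 30, seed = 1L, ...) {
  simulate_session(sim, op, cfg, mode = "adaptive", decoder = decoder,
                   n_messages = n_messages, seed = seed, ...)
}

#' Plot a closed-loop ISI trace
#'
#' @param x the `trace` data.frame of a [simulate_session()] result.
#' @param ... passed to [plot()].
#' @export
plot_isi_trace <- function(x, ...) {
  plot(x$msg_index, x$isi_after, type = "s", xlab = "task message",
       ylab = "ISI [s]", ...)
  points(x$msg_index, x$isi_after,
         pch = ifelse(x$detected %in% TRUE, 19, 1))
}
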