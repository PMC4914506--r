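# Shared builders for small in-code fixtures.

# small scaled-down simulation: few channels, low raw rate (still an integer
# multiple of the 25 Hz classification rate)
small_sim <- function(...) {
  args <- utils::modifyList(list(n_channels = 16, fs_raw = 100,
                                 noise_white_sd = 1.5, noise_pink_sd = 1.3,
                                 artifact_rate = 0, seed = 42),
                            list(...))
  do.call(simulation_config, args)
}

small_cfg <- function(...) pipeline_config(fs_raw = 100, ...)

# deterministic, always-answering operator
prompt_operator <- function(latency = 3) {
  operator_model(rt_sampler = function(n) rep(latency, n),
                 p_miss = function(dt) rep(0, length(dt)))
}

# recording with a single sine per channel
sine_recording <- function(freqs, fs = 1000, dur = 10, amp = 1) {
  t <- (seq_len(dur * fs) - 1) / fs
  x <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t), numeric(length(t))))
  eeg_recording(x, fs, paste0("ch", seq_along(freqs)), "FCz")
}

# log with first messages at given onsets, answered at given latencies
# (NA latency = missed); offsets at +1.1 s
toy_message_log <- function(onsets, latencies) {
  rows <- list()
  for (i in seq_along(onsets)) {
    rows[[length(rows) + 1]] <- data.frame(time_s = onsets[i], kind = "msg_first",
                                           message_id = i)
    rows[[length(rows) + 1]] <- data.frame(time_s = onsets[i] + 1.1,
                                           kind = "msg_offset", message_id = i)
    if (!is.na(latencies[i]))
      rows[[length(rows) + 1]] <- data.frame(time_s = onsets[i] + latencies[i],
                                             kind = "response", message_id = i)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$time_s), ]
  event_log(df$time_s, df$kind, df$message_id)
}

# single-trial epoch set from a channels x samples matrix
one_epoch <- function(mat, fs = 25, labels = "target",
                      channels = paste0("ch", seq_len(nrow(mat)))) {
  epoch_set(array(mat, c(1, dim(mat))), fs, 0, labels, channels)
}

# independent amplitude estimate of one frequency component (DFT projection)
tone_amplitude <- function(x, fs, f) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  2 * sqrt(mean(x * sin(2 * pi * f * t))^2 + mean(x * cos(2 * pi * f * t))^2)
}
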