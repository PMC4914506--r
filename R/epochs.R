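#' Fixed-length labeled EEG epochs
#'
#' Trials x channels x samples array with per-trial labels and metadata
#' (preceding ISI, response latency, message id). `t0_offset` is the epoch
#' start relative to stimulus onset (0 for classification windows, -0.1 s for
#' ERP epochs). Windows are half-open `[t_on, t_off)`.
#'
#' @param epochs numeric array, trials x channels x samples (uV).
#' @param fs sampling rate in Hz.
#' @param t0_offset epoch start relative to the stimulus, s.
#' @param labels character vector, one per trial (e.g. `"target"`,
#'   `"standard"`).
#' @param channel_labels channel names.
#' @param meta data.frame of per-trial metadata (or NULL).
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, t0_offset = 0, labels,
                      channel_labels, meta = NULL) {
  assert_that(length(dim(epochs)) == 3, "`epochs` must be a 3-d array")
  assert_that(dim(epochs)[1] == length(labels),
              "labels length must equal trial count")
  assert_that(dim(epochs)[2] == length(channel_labels),
              "channel_labels length must equal channel count")
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(dim(epochs)[1]))
  assert_that(nrow(meta) == dim(epochs)[1], "meta must have one row per trial")
  structure(list(epochs = epochs, fs = fs, t0_offset = t0_offset,
                 labels = as.character(labels),
                 channel_labels = as.character(channel_labels), meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz (t0 %+g s)\n",
              d[1], d[2], d[3], x$fs, x$t0_offset))
  if (length(x$labels)) print(table(x$labels))
  invisible(x)
}

n_trials <- function(ep) dim(ep$epochs)[1]

subset_epochs <- function(ep, idx) {
  epoch_set(ep$epochs[idx, , , drop = FALSE], ep$fs, ep$t0_offset,
            ep$labels[idx], ep$channel_labels,
            ep$meta[idx, , drop = FALSE])
}

# preceding ISI per first message: offset-to-onset gap from the previous
# presentation (first or repeat) to this msg_first onset
preceding_isis <- function(log, presentation_s) {
  pres <- log[log$kind %in% c("msg_first", "msg_repeat"), , drop = FALSE]
  firsts_idx <- which(pres$kind == "msg_first")
  vapply(firsts_idx, function(i) {
    if (i == 1) NA_real_
    else pres$time_s[i] - (pres$time_s[i - 1] + presentation_s)
  }, numeric(1))
}

cut_window <- function(data, fs, t_on, n_win) {
  s0 <- floor(t_on * fs) + 1
  if (s0 < 1 || s0 + n_win - 1 > ncol(data)) return(NULL)
  data[, s0:(s0 + n_win - 1), drop = FALSE]
}

#' Cut target / standard windows for single-trial classification
#'
#' Segments a decimated recording into 1 s windows following the study's
#' labelling rules. Targets are windows starting at `msg_first` onsets
#' (repetitions never yield targets). In training mode a first message only
#' becomes a target if it was answered within
#' `cfg$training_latency_cutoff` (15 s, boundary inclusive); in online mode
#' every first message yields one candidate epoch regardless of the
#' response. Standards (training mode only) are cut on the 1 s grid anchored
#' at recording start, excluding any window whose `[start-1, end+1]`
#' envelope contains a task-relevant event (message presentation, offset, or
#' operator response). Windows exceeding the recording are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param rec decimated [eeg_recording()] (classification rate, 25 Hz).
#' @param log an [event_log()] aligned to `rec`.
#' @param cfg a [pipeline_config()].
#' @param mode `"train"` or `"online"`.
#' @return an [epoch_set()] with labels `"target"` / `"standard"` and
#'   per-trial metadata (message id, preceding ISI, response latency).
#' @export
extract_classification_epochs <- function(rec, log, cfg = pipeline_config(),
                                          mode = c("train", "online")) {
  mode <- match.arg(mode)
  n_win <- round(cfg$window_s * rec$fs)
  lat <- response_latencies(log)
  isis <- preceding_isis(log, cfg$presentation_s)
  n_skipped <- 0L

  trials <- list(); labels <- character(); meta <- list()
  add <- function(win, label, id, isi, latency, t_on) {
    trials[[length(trials) + 1L]] <<- win
    labels[length(labels) + 1L] <<- label
    meta[[length(meta) + 1L]] <<- data.frame(
      message_id = id, preceding_isi = isi, response_latency = latency,
      onset = t_on)
  }

  for (i in seq_len(nrow(lat))) {
    keep <- if (mode == "train") {
      !is.na(lat$latency[i]) && lat$latency[i] <= cfg$training_latency_cutoff
    } else TRUE
    if (!keep) next
    win <- cut_window(rec$data, rec$fs, lat$onset[i], n_win)
    if (is.null(win)) { n_skipped <- n_skipped + 1L; next }
    add(win, "target", lat$message_id[i], isis[i], lat$latency[i], lat$onset[i])
  }

  if (mode == "train") {
    relevant <- log$time_s[log$kind %in% c("msg_first", "msg_repeat",
                                           "msg_offset", "response")]
    t_max <- rec_duration(rec) - cfg$window_s
    for (t0 in seq(0, floor(t_max))) {
      if (any(relevant >= t0 - 1 & relevant <= t0 + cfg$window_s + 1)) next
      win <- cut_window(rec$data, rec$fs, t0, n_win)
      if (is.null(win)) { n_skipped <- n_skipped + 1L; next }
      add(win, "standard", NA_integer_, NA_real_, NA_real_, t0)
    }
  }

  if (length(trials) == 0) {
    ep <- epoch_set(array(0, c(0, n_channels(rec), n_win)), rec$fs, 0,
                    character(), rec$channel_labels)
  } else {
    arr <- array(0, c(length(trials), n_channels(rec), n_win))
    for (i in seq_along(trials)) arr[i, , ] <- trials[[i]]
    ep <- epoch_set(arr, rec$fs, 0, labels, rec$channel_labels,
                    do.call(rbind, meta))
  }
  if (n_skipped > 0)
    warning(sprintf("%d window(s) beyond recording end skipped", n_skipped))
  attr(ep, "n_skipped") <- n_skipped
  ep
}

#' Cut baseline-corrected ERP epochs
#'
#' Epochs of `cfg$erp_window` (-0.1..1.0 s) around `msg_first` onsets, with
#' the per-channel mean of the pre-stimulus interval (-0.1..0 s) subtracted.
#' Only answered first messages are used; `max_latency` additionally bounds
#' the response latency (the training analysis uses 15 s).
#'
#' @param rec band-passed, CAR-referenced [eeg_recording()].
#' @param log an [event_log()].
#' @param cfg a [pipeline_config()].
#' @param max_latency only messages answered within this latency (s) are
#'   epoched; `Inf` keeps all answered messages.
#' @return an [epoch_set()] with `t0_offset = cfg$erp_window[1]`.
#' @export
extract_erp_epochs <- function(rec, log, cfg = pipeline_config(),
                               max_latency = Inf) {
  w <- cfg$erp_window
  n_win <- round((w[2] - w[1]) * rec$fs)
  n_base <- round(-w[1] * rec$fs)
  lat <- response_latencies(log)
  isis <- preceding_isis(log, cfg$presentation_s)
  n_skipped <- 0L
  trials <- list(); meta <- list()
  for (i in seq_len(nrow(lat))) {
    if (is.na(lat$latency[i]) || lat$latency[i] > max_latency) next
    win <- cut_window(rec$data, rec$fs, lat$onset[i] + w[1], n_win)
    if (is.null(win)) { n_skipped <- n_skipped + 1L; next }
    if (n_base > 0)
      win <- win - rowMeans(win[, seq_len(n_base), drop = FALSE])
    trials[[length(trials) + 1L]] <- win
    meta[[length(meta) + 1L]] <- data.frame(
      message_id = lat$message_id[i], preceding_isi = isis[i],
      response_latency = lat$latency[i], onset = lat$onset[i])
  }
  if (length(trials) == 0) {
    ep <- epoch_set(array(0, c(0, n_channels(rec), n_win)), rec$fs, w[1],
                    character(), rec$channel_labels)
  } else {
    arr <- array(0, c(length(trials), n_channels(rec), n_win))
    for (i in seq_along(trials)) arr[i, , ] <- trials[[i]]
    ep <- epoch_set(arr, rec$fs, w[1], rep("target", length(trials)),
                    rec$channel_labels, do.call(rbind, meta))
  }
  if (n_skipped > 0)
    warning(sprintf("%d epoch(s) beyond recording end skipped", n_skipped))
  attr(ep, "n_skipped") <- n_skipped
  ep
}

#' Amplitude-based artifact rejection
#'
#' A trial is rejected iff any sample on any channel strictly exceeds
#' `abs_uv` in absolute value; a sample exactly at the bound is kept.
#'
#' @param ep an [epoch_set()].
#' @param abs_uv rejection bound in uV (study value: 100).
#' @return list with `kept` (an [epoch_set()]) and `rejected` (integer trial
#'   indices of the input).
#' @export
reject_artifacts <- function(ep, abs_uv = 100) {
  assert_that(abs_uv > 0, "abs_uv must be > 0")
  nt <- n_trials(ep)
  bad <- vapply(seq_len(nt), function(i)
    any(abs(ep$epochs[i, , ]) > abs_uv), logical(1))
  list(kept = subset_epochs(ep, which(!bad)), rejected = which(bad))
}
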