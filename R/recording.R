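#' Continuous multichannel EEG recording
#'
#' Container for a continuous recording: a channels x samples matrix in
#' microvolts, its sampling rate, ordered channel labels and the name of the
#' recording reference electrode (the reference itself is not a data row;
#' it can be reconstructed as a zero channel by [rereference_car()]).
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_labels character vector, one unique label per row of `data`.
#' @param reference_label name of the recording reference electrode
#'   (default `"FCz"`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, reference_label = "FCz") {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  assert_that(is.matrix(data) && is.numeric(data), "`data` must be a numeric matrix")
  assert_that(is.numeric(fs) && length(fs) == 1 && fs > 0, "`fs` must be a positive scalar")
  assert_that(length(channel_labels) == nrow(data),
              "need %d channel labels, got %d", nrow(data), length(channel_labels))
  assert_that(!anyDuplicated(channel_labels), "duplicated channel labels")
  assert_that(all(is.finite(data)), "recording contains non-finite samples")
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 reference_label = reference_label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference_label))
  invisible(x)
}

#' Number of channels / samples / duration of a recording
#' @param rec an [eeg_recording()].
#' @return integer count or duration in seconds.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_channels
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs
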