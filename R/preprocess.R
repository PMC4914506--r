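# Online-capable preprocessing: causal DC removal, FIR anti-alias
# decimation, zero-phase ERP band-pass, and common average re-referencing
# with reconstruction of the recording reference channel.

#' Causal DC removal
#'
#' First-order high-pass realized as `y = x - m`, where `m` is an
#' exponentially forgetting running mean with the given time constant. A
#' single forward pass with finite state, hence usable online; the output of
#' any window much longer than the time constant is centered around zero.
#'
#' @param rec an [eeg_recording()].
#' @param time_constant forgetting time constant in seconds (> 0).
#' @return the filtered [eeg_recording()].
#' @export
dc_remove <- function(rec, time_constant = 2) {
  assert_that(time_constant > 0, "time_constant must be > 0")
  alpha <- exp(-1 / (rec$fs * time_constant))
  out <- rec
  # running mean m[n] = alpha m[n-1] + (1-alpha) x[n]  (per channel)
  for (i in seq_len(n_channels(rec))) {
    m <- stats::filter((1 - alpha) * rec$data[i, ], alpha,
                       method = "recursive")
    out$data[i, ] <- rec$data[i, ] - as.numeric(m)
  }
  out
}

# linear-phase FIR low-pass: passband edge `cutoff`, stopband edge `stop_hz`,
# Hamming window; >= 50 dB attenuation beyond the stopband edge
design_antialias <- function(fs, cutoff, stop_hz) {
  trans <- stop_hz - cutoff
  n <- ceiling(3.3 * fs / trans)
  if (n %% 2 == 1) n <- n + 1  # even order -> integer group delay n/2
  wc <- (cutoff + stop_hz) / 2 / (fs / 2)
  signal::fir1(n, wc, type = "low")
}

fir_filter_channels <- function(x, b, phase = c("causal", "zero")) {
  phase <- match.arg(phase)
  n <- ncol(x)
  nb <- length(b)
  delay <- (nb - 1) / 2
  out <- matrix(0, nrow(x), n)
  for (i in seq_len(nrow(x))) {
    if (phase == "causal") {
      out[i, ] <- signal::fftfilt(b, x[i, ])[seq_len(n)]
    } else {
      y <- signal::fftfilt(b, c(x[i, ], numeric(nb)))
      out[i, ] <- y[(delay + 1):(delay + n)]
    }
  }
  out
}

#' Anti-alias filtered decimation
#'
#' Low-pass filters at `cutoff` (linear-phase FIR; the transition band ends
#' well below the new Nyquist frequency) and keeps every
#' `fs/fs_out`-th sample in a single integer-factor step. The online path
#' applies the filter causally; the offline path compensates the FIR group
#' delay (zero phase).
#'
#' @param rec an [eeg_recording()].
#' @param fs_out target rate in Hz; must divide `rec$fs`.
#' @param cutoff anti-alias passband edge in Hz (study value: 4).
#' @param phase `"zero"` (offline, delay-compensated) or `"causal"` (online).
#' @param stop_hz stopband edge in Hz; defaults to `fs_out/2 * 0.8` or
#'   `2.5 * cutoff`, whichever is smaller, keeping 10 Hz activity out of a
#'   25 Hz output stream.
#' @return the decimated [eeg_recording()].
#' @export
decimate_recording <- function(rec, fs_out, cutoff = 4,
                               phase = c("zero", "causal"),
                               stop_hz = min(0.8 * fs_out / 2, 2.5 * cutoff)) {
  phase <- match.arg(phase)
  r <- rec$fs / fs_out
  assert_that(abs(r - round(r)) < 1e-9, "fs_out (%g) must divide fs (%g)",
              fs_out, rec$fs)
  r <- round(r)
  assert_that(cutoff < fs_out / 2, "cutoff must be below the new Nyquist")
  assert_that(stop_hz > cutoff && stop_hz <= fs_out / 2,
              "stopband edge must lie in (cutoff, fs_out/2]")
  b <- design_antialias(rec$fs, cutoff, stop_hz)
  y <- fir_filter_channels(rec$data, b, phase)
  keep <- seq(1, by = r, length.out = floor(ncol(y) / r))
  out <- rec
  out$data <- y[, keep, drop = FALSE]
  out$fs <- fs_out
  out
}

#' Zero-phase ERP band-pass
#'
#' Forward-backward Butterworth filtering (order-2 high-pass cascaded with an
#' order-4 low-pass), for the offline ERP-average path. Length preserving,
#' zero phase.
#'
#' @param rec an [eeg_recording()].
#' @param band numeric `c(low, high)` in Hz (study value: 0.1-30).
#' @return the filtered [eeg_recording()].
#' @export
bandpass_erp <- function(rec, band = c(0.1, 30)) {
  assert_that(band[1] > 0 && band[1] < band[2] && band[2] < rec$fs / 2,
              "need 0 < low < high < fs/2")
  hp <- signal::butter(2, band[1] / (rec$fs / 2), type = "high")
  lp <- signal::butter(4, band[2] / (rec$fs / 2), type = "low")
  out <- rec
  for (i in seq_len(n_channels(rec))) {
    y <- signal::filtfilt(hp, rec$data[i, ])
    out$data[i, ] <- signal::filtfilt(lp, y)
  }
  out
}

#' Common average reference with reference reconstruction
#'
#' Re-expresses the recording in a common average reference. With
#' `add_reference = TRUE` (the default, matching data recorded against a
#' physical reference such as FCz) the reference electrode is first
#' reconstructed as an all-zero channel appended under its label; the
#' instantaneous mean over all channels is then subtracted from every
#' channel, so each output sample sums to zero across channels. With
#' `add_reference = FALSE` the plain CAR map is applied to the channels as
#' given; this pure form is invariant to adding a common offset to all
#' channels (with reconstruction, the zero reference row pins the offset).
#'
#' @param rec an [eeg_recording()].
#' @param add_reference reconstruct `rec$reference_label` as a zero channel
#'   before averaging.
#' @return an [eeg_recording()] with reference label `"CAR"`.
#' @export
rereference_car <- function(rec, add_reference = TRUE) {
  if (add_reference) {
    assert_that(!rec$reference_label %in% rec$channel_labels,
                "recording already contains its reference channel")
    x <- rbind(rec$data, 0)
    labels <- c(rec$channel_labels, rec$reference_label)
  } else {
    x <- rec$data
    labels <- rec$channel_labels
  }
  x <- sweep(x, 2, colMeans(x))
  eeg_recording(x, rec$fs, labels, "CAR")
}
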