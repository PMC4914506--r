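#' Average ERP over selected trials
#'
#' Arithmetic mean per channel and sample over the selected trials of an
#' artifact-rejected, baseline-corrected epoch set.
#'
#' @param ep an [epoch_set()].
#' @param select logical or integer trial selector (default: all trials).
#' @param condition free-text condition tag stored with the average.
#' @return object of class `erp_average`: `mean` (channels x samples), `fs`,
#'   `t0_offset`, `n_trials`, `condition`, `channel_labels`.
#' @export
average_erp <- function(ep, select = NULL, condition = "all") {
  idx <- if (is.null(select)) seq_len(n_trials(ep))
         else if (is.logical(select)) which(select) else select
  assert_that(length(idx) >= 1, "trial selection is empty")
  m <- apply(ep$epochs[idx, , , drop = FALSE], c(2, 3), mean)
  structure(list(mean = m, fs = ep$fs, t0_offset = ep$t0_offset,
                 n_trials = length(idx), condition = condition,
                 channel_labels = ep$channel_labels),
            class = "erp_average")
}

#' @export
print.erp_average <- function(x, ...) {
  cat(sprintf("<erp_average> '%s': %d trials, %d channels x %d samples @ %g Hz\n",
              x$condition, x$n_trials, nrow(x$mean), ncol(x$mean), x$fs))
  invisible(x)
}

#' @export
plot.erp_average <- function(x, channel = "Pz", ...) {
  i <- match(channel, x$channel_labels)
  assert_that(!is.na(i), "no channel '%s'", channel)
  t <- x$t0_offset + (seq_len(ncol(x$mean)) - 1) / x$fs
  plot(t, x$mean[i, ], type = "l", xlab = "time [s]",
       ylab = sprintf("%s [uV]", channel), ...)
  abline(v = 0, lty = 3)
}

#' Positive-peak detection in an averaged ERP
#'
#' Maximum of the averaged waveform at one channel within the peak window
#' (study value 0.3-0.7 s post-stimulus); among tied maxima the earliest
#' latency is returned.
#'
#' @param avg an [average_erp()] result.
#' @param channel channel label.
#' @param window `c(from, to)` seconds relative to stimulus onset.
#' @return list with `latency` (s) and `amplitude` (uV).
#' @export
detect_peak <- function(avg, channel = "Pz", window = c(0.3, 0.7)) {
  i <- match(channel, avg$channel_labels)
  assert_that(!is.na(i), "no channel '%s'", channel)
  t <- avg$t0_offset + (seq_len(ncol(avg$mean)) - 1) / avg$fs
  inside <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  assert_that(length(inside) > 0, "peak window outside the epoch")
  y <- avg$mean[i, inside]
  k <- inside[which.max(y)]               # which.max: first maximum = earliest
  list(latency = t[k], amplitude = avg$mean[i, k])
}

#' Split adaptive-run trials into ISI-short and ISI-long groups
#'
#' Per-subject median split on the preceding ISI recorded with each trial:
#' trials at or below the median go to the short group, the rest to the long
#' group. When all preceding ISIs are equal no split exists and the result
#' is flagged degenerate.
#'
#' @param ep an [epoch_set()] with `preceding_isi` metadata.
#' @return list with integer index vectors `short` and `long`, the `median`
#'   used, and `degenerate` flag.
#' @export
group_trials_by_isi <- function(ep) {
  isi <- ep$meta$preceding_isi
  assert_that(!is.null(isi), "epochs carry no preceding-ISI metadata")
  ok <- which(!is.na(isi))
  assert_that(length(ok) > 0, "no trials with preceding-ISI metadata")
  med <- stats::median(isi[ok])
  short <- ok[isi[ok] <= med]
  long <- ok[isi[ok] > med]
  list(short = short, long = long, median = med,
       degenerate = length(unique(isi[ok])) == 1)
}
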