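#' Segment grid for local straight-line features
#'
#' Segment start times `0, seg_step, ...` while `start + seg_len <= window`
#' (study values 400 ms length, 120 ms step, 1 s window: six segments per
#' channel).
#'
#' @param window_s window length, s.
#' @param seg_len_s segment length, s.
#' @param seg_step_s step between segment starts, s.
#' @return data.frame with columns `start_s`, `len_s`.
#' @export
feature_grid <- function(window_s = 1, seg_len_s = 0.4, seg_step_s = 0.12) {
  starts <- seq(0, window_s - seg_len_s + 1e-9, by = seg_step_s)
  data.frame(start_s = starts, len_s = seg_len_s)
}

#' Local straight-line (slope) features
#'
#' For every trial, channel and grid segment, fits an ordinary least-squares
#' line to the samples of the segment and keeps its slope (uV/s). Features
#' are ordered channel-major, segment-minor; with 8 pseudo-channels and the
#' study grid this yields 48 features per trial.
#'
#' @param ep an [epoch_set()] of classification windows (25 Hz, 1 s).
#' @param cfg a [pipeline_config()] supplying the grid.
#' @return numeric matrix trials x features, with the grid as attribute
#'   `"grid"` and feature names `<channel>.s<k>`.
#' @export
slope_features <- function(ep, cfg = pipeline_config()) {
  grid <- feature_grid(cfg$window_s, cfg$seg_len_s, cfg$seg_step_s)
  fs <- ep$fs
  d <- dim(ep$epochs)
  seg_idx <- lapply(seq_len(nrow(grid)), function(g) {
    a <- round(grid$start_s[g] * fs) + 1
    b <- a + round(grid$len_s[g] * fs) - 1
    assert_that(b - a + 1 >= 2, "segment %d has fewer than 2 samples", g)
    assert_that(b <= d[3], "segment %d exceeds the window", g)
    a:b
  })
  # precompute centered time regressor per segment: slope = sum(tc*y)/sum(tc^2)
  tw <- lapply(seg_idx, function(ii) {
    t <- (ii - 1) / fs
    tc <- t - mean(t)
    tc / sum(tc^2)
  })
  nf <- d[2] * nrow(grid)
  out <- matrix(0, d[1], nf)
  for (i in seq_len(d[1])) {
    x <- ep$epochs[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = d[2])
    f <- 0L
    for (ch in seq_len(d[2]))
      for (g in seq_along(seg_idx)) {
        f <- f + 1L
        out[i, f] <- sum(x[ch, seg_idx[[g]]] * tw[[g]])
      }
  }
  colnames(out) <- as.vector(t(outer(ep$channel_labels,
                                     paste0("s", seq_len(nrow(grid))),
                                     paste, sep = ".")))
  attr(out, "grid") <- grid
  out
}
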