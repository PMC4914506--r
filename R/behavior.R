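#' Behavioral summary of a session
#'
#' Behavioral metrics of one run, computed from the event log alone:
#' * `total_runtime`: time between the 1st and the 30th (or `n_messages`-th)
#'   first task message; if fewer first messages exist the available span is
#'   used and `runtime_truncated` is set.
#' * `median_rt`: median response latency over answered first messages
#'   (repetitions excluded).
#' * `n_late`: answered first messages with latency above `late_cutoff`
#'   (study value 15 s).
#' * `n_missed`: first messages never answered.
#' * `mean_isi`: mean offset-to-onset gap between consecutive presentations.
#'
#' @param log an [event_log()].
#' @param cfg a [pipeline_config()].
#' @param n_messages nominal number of first messages per run.
#' @param late_cutoff late-response bound in seconds.
#' @return list of class `behavioral_summary`.
#' @export
behavioral_summary <- function(log, cfg = pipeline_config(), n_messages = 30,
                               late_cutoff = cfg$training_latency_cutoff) {
  lat <- response_latencies(log)
  assert_that(nrow(lat) >= 1, "log contains no first task messages")
  truncated <- nrow(lat) < n_messages
  k <- min(n_messages, nrow(lat))
  runtime <- lat$onset[k] - lat$onset[1]
  answered <- lat$latency[!is.na(lat$latency)]
  assert_that(length(answered) > 0, "no answered messages: median undefined")
  pres <- log[log$kind %in% c("msg_first", "msg_repeat"), , drop = FALSE]
  gaps <- if (nrow(pres) >= 2)
    pres$time_s[-1] - (pres$time_s[-nrow(pres)] + cfg$presentation_s)
  else numeric()
  structure(list(total_runtime = runtime,
                 median_rt = stats::median(answered),
                 n_late = sum(answered > late_cutoff),
                 n_missed = sum(is.na(lat$latency)),
                 n_answered = length(answered),
                 n_first = nrow(lat),
                 mean_isi = if (length(gaps)) mean(gaps) else NA_real_,
                 runtime_truncated = truncated),
            class = "behavioral_summary")
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat(sprintf(paste0("<behavioral_summary> runtime %.1f s%s, median RT %.2f s, ",
                     "%d late, %d missed of %d messages, mean ISI %.2f s\n"),
              x$total_runtime, if (x$runtime_truncated) " (truncated)" else "",
              x$median_rt, x$n_late, x$n_missed, x$n_first, x$mean_isi))
  invisible(x)
}

#' Paired condition tests (Friedman + Wilcoxon with Holm correction)
#'
#' Omnibus Friedman test over `k` paired conditions, followed by all
#' pairwise Wilcoxon signed-rank tests with Bonferroni-Holm adjustment.
#' Zero-difference pairs are dropped (standard signed-rank convention); a
#' comparison with no nonzero differences is degenerate and reported with
#' `p = NA` and the flag set. The exact permutation distribution is used for
#' n <= 15 nonzero pairs (unless ties force the normal approximation).
#'
#' @param values numeric matrix, subjects x conditions (colnames used as
#'   condition names).
#' @return list with `friedman` (statistic, df, p) and `pairwise`
#'   (data.frame of comparisons with raw and Holm-adjusted p-values).
#' @export
paired_condition_tests <- function(values) {
  values <- as.matrix(values)
  assert_that(nrow(values) >= 2 && ncol(values) >= 2,
              "need >= 2 subjects and >= 2 conditions")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("cond", seq_len(ncol(values)))
  fr <- stats::friedman.test(values)
  pairs <- utils::combn(ncol(values), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- values[, a] - values[, b]
    nz <- d[d != 0]
    if (length(nz) == 0) {
      return(data.frame(a = colnames(values)[a], b = colnames(values)[b],
                        n = 0L, p = NA_real_, degenerate = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(
      values[, a], values[, b], paired = TRUE,
      exact = length(nz) <= 15))
    data.frame(a = colnames(values)[a], b = colnames(values)[b],
               n = length(nz), p = wt$p.value, degenerate = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_holm <- NA_real_
  ok <- !is.na(pw$p)
  pw$p_holm[ok] <- stats::p.adjust(pw$p[ok], method = "holm")
  list(friedman = list(statistic = unname(fr$statistic),
                       df = unname(fr$parameter), p = fr$p.value),
       pairwise = pw)
}

#' Spearman rank correlation
#'
#' Midrank-based Spearman correlation, e.g. between per-run mean ISI and
#' total runtime.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho` and `p`.
#' @export
rank_correlation <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 2,
              "need paired vectors of length >= 2")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
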