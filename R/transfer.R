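#' Classifier-transfer evaluation over a set of runs
#'
#' Evaluates single-trial classification across runs following the study's
#' evaluation designs: *baseline* (train and test within the same fixed-ISI
#' condition), *transfer* (train on fixed-ISI runs, test on an adaptive
#' run), and the *fair-comparison* variant in which a decoder is trained on
#' a single run and results over the alternative training runs are averaged
#' by the caller. Each design row names its training run(s) and one test
#' run; the decoder (xDAWN + slope features + SVM + threshold) is fitted on
#' the training runs and balanced accuracy / AUC are computed on the test
#' run's target and standard epochs.
#'
#' @param runs named list; each element a list with `recording` (raw-rate
#'   [eeg_recording()]) and `events` ([event_log()]).
#' @param designs data.frame with columns `design` (label), `train`
#'   (run names, `"+"`-separated) and `test` (one run name).
#' @param cfg a [pipeline_config()].
#' @param seed RNG seed for decoder cross-validation.
#' @return data.frame with one row per design: bACC, AUC, TPR, TNR, chosen
#'   complexity and class counts.
#' @export
transfer_evaluation <- function(runs, designs, cfg = pipeline_config(),
                                seed = 1L) {
  assert_that(nrow(designs) >= 1, "empty design table")
  prep <- lapply(runs, function(r) {
    dec <- decimate_recording(dc_remove(r$recording, cfg$dc_time_constant),
                              cfg$fs_dec, cfg$anti_alias_cutoff,
                              phase = "causal")
    list(rec = dec, events = r$events)
  })
  out <- lapply(seq_len(nrow(designs)), function(i) {
    tr_names <- strsplit(designs$train[i], "\\s*\\+\\s*")[[1]]
    te_name <- designs$test[i]
    missing <- setdiff(c(tr_names, te_name), names(prep))
    assert_that(length(missing) == 0, "design '%s' references missing run(s): %s",
                designs$design[i], paste(missing, collapse = ", "))
    model <- fit_p300_decoder(lapply(tr_names, function(n) runs[[n]]$recording),
                              lapply(tr_names, function(n) runs[[n]]$events),
                              cfg, seed = seed)
    te <- prep[[te_name]]
    ep <- extract_classification_epochs(te$rec, te$events, cfg, "train")
    assert_that(any(ep$labels == "target") && any(ep$labels == "standard"),
                "test run '%s' lacks a class", te_name)
    pr <- predict(model, ep)
    m <- compute_metrics(pr$score, ep$labels, model$theta)
    data.frame(design = designs$design[i], train = designs$train[i],
               test = te_name, bACC = m$bACC, AUC = m$AUC,
               TPR = m$TPR, TNR = m$TNR, C = model$C,
               n_test_targets = sum(ep$labels == "target"),
               n_test_standards = sum(ep$labels == "standard"))
  })
  do.call(rbind, out)
}
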