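#' Balanced accuracy, TPR/TNR and AUC from scores
#'
#' `bACC = (TPR + TNR) / 2` with `detected = score > threshold` (strict).
#' AUC is the rank-sum statistic over target/standard score pairs with
#' midrank tie handling (a tied pair counts 1/2).
#'
#' @param scores numeric decision values, positive side = target.
#' @param labels character/logical labels; `"target"`/`TRUE` is the positive
#'   class.
#' @param threshold decision threshold (default 0).
#' @return list with `bACC`, `AUC`, `TPR`, `TNR`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0) {
  pos <- labels == "target" | labels == TRUE
  nT <- sum(pos); nS <- sum(!pos)
  assert_that(nT >= 1 && nS >= 1, "need at least one example of each class")
  tpr <- mean(scores[pos] > threshold)
  tnr <- mean(scores[!pos] <= threshold)
  r <- rank(scores)                       # midranks
  auc <- (sum(r[pos]) - nT * (nT + 1) / 2) / (nT * nS)
  list(bACC = (tpr + tnr) / 2, AUC = auc, TPR = tpr, TNR = tnr)
}

#' Balanced-accuracy threshold optimization
#'
#' Shifts the decision threshold away from the SVM's native 0 to the value
#' maximizing training-set balanced accuracy. Candidates are the midpoints
#' between consecutive sorted unique scores plus guards below the minimum
#' and above the maximum; among ties the threshold closest to 0 wins (then
#' the smaller one, for determinism). Because 0 lies inside one of the
#' candidate intervals, the optimized threshold never has lower training
#' bACC than the unshifted decision.
#'
#' @param scores training decision values.
#' @param labels training labels (`"target"` positive).
#' @return the optimized threshold.
#' @export
optimize_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  bacc <- vapply(cand, function(th)
    compute_metrics(scores, labels, th)$bACC, numeric(1))
  best <- which(bacc >= max(bacc) - 1e-12)
  best <- best[order(abs(cand[best]), cand[best])]
  cand[best[1]]
}
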