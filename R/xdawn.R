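# xDAWN spatial filtering: least-squares estimate of the evoked response via
# an overlap-aware Toeplitz 0/1 design matrix, then filters maximizing the
# signal-to-signal-plus-noise ratio (generalized Rayleigh quotient of the
# evoked covariance against the total signal covariance, solved by Cholesky
# whitening + symmetric eigendecomposition).

#' Fit an xDAWN spatial filter
#'
#' Estimates the stimulus-locked evoked response by least squares with a
#' Toeplitz 0/1 design aligned at the target onsets (overlapping responses
#' are handled by the design matrix, not averaged away), then solves
#' `Cs w = lambda Cx w` for filters `w`, where `Cs` is the covariance of the
#' reconstructed evoked signal and `Cx` the total signal covariance.
#' Components are ordered by decreasing ratio; the model keeps all of them
#' and marks the top `n_selected` (study value: 8 pseudo-channels) for
#' application. Filters have unit norm; each is signed so that the largest
#' absolute entry of its spatial pattern is positive.
#'
#' @param rec decimated training [eeg_recording()].
#' @param target_onsets `msg_first` onset times in seconds (>= 2).
#' @param window_s evoked-response window length, s (study value: 1).
#' @param n_selected number of pseudo-channels to retain.
#' @param variant `"toeplitz"` (overlap-aware least squares) or `"average"`
#'   (epoch-average shortcut, for cross-checking).
#' @param ridge relative ridge added to a rank-deficient covariance
#'   (`ridge * trace/dim`), with a warning.
#' @return object of class `xdawn_filter` with elements `W` (channels x
#'   components), `A` (spatial patterns), `ratios`, `n_selected`, `fs`,
#'   `channel_labels`.
#' @export
fit_xdawn <- function(rec, target_onsets, window_s = 1, n_selected = 8,
                      variant = c("toeplitz", "average"), ridge = 1e-6) {
  variant <- match.arg(variant)
  assert_that(length(target_onsets) >= 2, "need at least 2 target onsets")
  fs <- rec$fs
  X <- t(rec$data)                       # samples x channels
  N <- nrow(X); C <- ncol(X)
  L <- round(window_s * fs)
  s0 <- floor(target_onsets * fs) + 1
  assert_that(all(s0 >= 1 & s0 + L - 1 <= N), "window extends beyond recording")

  D <- matrix(0, N, L)
  for (s in s0) D[cbind(s:(s + L - 1), 1:L)] <- 1

  A_hat <- tryCatch(qr.solve(D, X), error = function(e)
    qr.solve(crossprod(D) + diag(1e-10, L), crossprod(D, X)))
  if (variant == "average") {
    A_hat <- Reduce(`+`, lapply(s0, function(s) X[s:(s + L - 1), , drop = FALSE])) /
      length(s0)
    S <- matrix(0, N, C)
    for (s in s0) S[s:(s + L - 1), ] <- S[s:(s + L - 1), ] + A_hat
  } else {
    S <- D %*% A_hat
  }

  Cs <- crossprod(S) / N
  Cx <- crossprod(X) / N
  R <- tryCatch(chol(Cx), error = function(e) NULL)
  if (is.null(R)) {
    warning("total covariance is rank deficient; applying ridge regularization")
    Cx <- Cx + diag(ridge * sum(diag(Cx)) / C, C)
    R <- chol(Cx)
  }
  Ri <- backsolve(R, diag(C))            # inverse of the Cholesky factor
  M <- crossprod(Ri, Cs) %*% Ri          # t(Ri) %*% Cs %*% Ri, symmetric
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- Ri %*% eg$vectors                 # generalized eigenvectors, ratio desc
  ratios <- eg$values

  A <- Cx %*% W                          # spatial patterns (up to scale)
  for (j in seq_len(C)) {
    if (A[which.max(abs(A[, j])), j] < 0) { W[, j] <- -W[, j]; A[, j] <- -A[, j] }
    nrm <- sqrt(sum(W[, j]^2))
    W[, j] <- W[, j] / nrm
    A[, j] <- A[, j] / nrm
  }
  structure(list(W = W, A = A, ratios = ratios,
                 n_selected = min(n_selected, C), fs = fs,
                 channel_labels = rec$channel_labels,
                 evoked = A_hat, variant = variant),
            class = "xdawn_filter")
}

#' @export
print.xdawn_filter <- function(x, ...) {
  cat(sprintf("<xdawn_filter> %d channels -> %d of %d components; top ratios: %s\n",
              nrow(x$W), x$n_selected, ncol(x$W),
              paste(signif(utils::head(x$ratios, 3), 3), collapse = ", ")))
  invisible(x)
}

#' Project epochs onto xDAWN pseudo-channels
#'
#' Applies the top `n_selected` filters to every trial: each output
#' pseudo-channel is `w' x` per sample.
#'
#' @param model an [fit_xdawn()] result.
#' @param ep an [epoch_set()] whose channel order matches the model's.
#' @return an [epoch_set()] of trials x n_selected x samples with channel
#'   labels `XD1..XDk`.
#' @export
apply_spatial_filter <- function(model, ep) {
  if (!identical(model$channel_labels, ep$channel_labels)) {
    bad <- union(setdiff(model$channel_labels, ep$channel_labels),
                 setdiff(ep$channel_labels, model$channel_labels))
    if (length(bad) == 0) bad <- "channel order differs"
    stopf("epoch channels do not match the spatial filter: %s",
          paste(bad, collapse = ", "))
  }
  k <- model$n_selected
  Wk <- model$W[, seq_len(k), drop = FALSE]
  d <- dim(ep$epochs)
  out <- array(0, c(d[1], k, d[3]))
  for (i in seq_len(d[1]))
    out[i, , ] <- crossprod(Wk, ep$epochs[i, , ])
  epoch_set(out, ep$fs, ep$t0_offset, ep$labels,
            paste0("XD", seq_len(k)), ep$meta)
}
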