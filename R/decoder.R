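# Decoder training: z-scored slope features -> linear SVM with an internal
# stratified five-fold cross-validated complexity grid search
# (C = 10^0..10^-6) -> balanced-accuracy threshold optimization. The fitted
# object is a pure linear scorer, so classification is deterministic.

svm_linear_weights <- function(fit, feature_names) {
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  list(w = w, b = b)
}

fit_linear_svm <- function(X, y, cost) {
  # y: factor with levels c("target", "standard")
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  wb <- svm_linear_weights(fit)
  s <- as.numeric(X %*% wb$w + wb$b)
  # libsvm's decision sign depends on which class it saw first; orient so
  # targets score positive
  if (mean(s[y == "target"]) < mean(s[y == "standard"])) {
    wb$w <- -wb$w; wb$b <- -wb$b
  }
  wb
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the single-trial P300 decoder
#'
#' Applies the spatial filter, extracts slope features, z-scores them on the
#' training data, selects the SVM complexity from the grid
#' `10^cfg$complexity_exponents` by stratified `cfg$cv_folds`-fold
#' cross-validated balanced accuracy (threshold optimized on each training
#' fold; ties broken toward the larger C), refits on all data with the
#' chosen complexity, and optimizes the final decision threshold on the
#' training scores.
#'
#' @param target_ep,standard_ep [epoch_set()]s of raw-channel classification
#'   windows for the two classes.
#' @param cfg a [pipeline_config()].
#' @param spatial an [fit_xdawn()] model.
#' @param seed RNG seed for the cross-validation folds.
#' @return object of class `p300_decoder`: spatial model, feature scaler,
#'   weight vector, bias, chosen complexity `C`, threshold `theta`, CV table
#'   and training metadata.
#' @export
train_decoder <- function(target_ep, standard_ep, cfg = pipeline_config(),
                          spatial, seed = 1L) {
  assert_that(inherits(spatial, "xdawn_filter"), "`spatial` must be an xdawn_filter")
  nt <- n_trials(target_ep); ns <- n_trials(standard_ep)
  assert_that(nt >= cfg$cv_folds && ns >= cfg$cv_folds,
              "need >= %d examples per class, got %d targets / %d standards",
              cfg$cv_folds, nt, ns)
  Xt <- slope_features(apply_spatial_filter(spatial, target_ep), cfg)
  Xs <- slope_features(apply_spatial_filter(spatial, standard_ep), cfg)
  X <- rbind(Xt, Xs)
  y <- factor(rep(c("target", "standard"), c(nt, ns)),
              levels = c("target", "standard"))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xz <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  grid <- 10^cfg$complexity_exponents
  cv <- with_seed(seed, {
    fold <- stratified_folds(y, cfg$cv_folds)
    vapply(grid, function(cost) {
      baccs <- vapply(seq_len(cfg$cv_folds), function(k) {
        tr <- fold != k
        wb <- fit_linear_svm(Xz[tr, , drop = FALSE], y[tr], cost)
        s_tr <- as.numeric(Xz[tr, , drop = FALSE] %*% wb$w + wb$b)
        th <- optimize_threshold(s_tr, y[tr])
        s_te <- as.numeric(Xz[!tr, , drop = FALSE] %*% wb$w + wb$b)
        compute_metrics(s_te, y[!tr], th)$bACC
      }, numeric(1))
      mean(baccs)
    }, numeric(1))
  })
  best <- which(cv >= max(cv) - 1e-12)[1]   # grid is ordered largest C first
  wb <- fit_linear_svm(Xz, y, grid[best])
  scores <- as.numeric(Xz %*% wb$w + wb$b)
  theta <- optimize_threshold(scores, y)

  structure(list(spatial = spatial, cfg = cfg,
                 scaler = list(mu = mu, sd = sdv),
                 w = wb$w, b = wb$b, C = grid[best], theta = theta,
                 cv = data.frame(C = grid, cv_bACC = cv),
                 n_targets = nt, n_standards = ns,
                 train_metrics = compute_metrics(scores, y, theta)),
            class = "p300_decoder")
}

#' Fit the full decoding chain from continuous recordings
#'
#' Convenience front end: DC removal, decimation to the classification rate,
#' target/standard window extraction in training mode, xDAWN fit on the
#' concatenated runs, then [train_decoder()]. Accepts one run or a list of
#' runs (recordings with matching event logs), which are concatenated along
#' time for the spatial-filter fit and pooled for classifier training.
#'
#' @param recordings an [eeg_recording()] or list of them (raw rate).
#' @param logs an [event_log()] or list matching `recordings`.
#' @param cfg a [pipeline_config()].
#' @param seed RNG seed for cross-validation.
#' @return a `p300_decoder`.
#' @export
fit_p300_decoder <- function(recordings, logs, cfg = pipeline_config(),
                             seed = 1L) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  if (inherits(logs, "event_log")) logs <- list(logs)
  assert_that(length(recordings) == length(logs),
              "need one event log per recording")
  dec <- lapply(recordings, function(r)
    decimate_recording(dc_remove(r, cfg$dc_time_constant), cfg$fs_dec,
                       cfg$anti_alias_cutoff, phase = "causal"))
  eps <- Map(function(r, l) extract_classification_epochs(r, l, cfg, "train"),
             dec, logs)
  cat_data <- do.call(cbind, lapply(dec, function(r) r$data))
  cat_rec <- eeg_recording(cat_data, cfg$fs_dec, dec[[1]]$channel_labels,
                           dec[[1]]$reference_label)
  offs <- cumsum(c(0, vapply(dec, rec_duration, numeric(1))))
  onsets <- unlist(Map(function(ep, o) {
    m <- ep$meta[ep$labels == "target", , drop = FALSE]
    m$onset + o
  }, eps, offs[seq_along(eps)]))
  spatial <- fit_xdawn(cat_rec, onsets, cfg$window_s, cfg$n_pseudo)
  tg <- lapply(eps, function(e) subset_epochs(e, which(e$labels == "target")))
  st <- lapply(eps, function(e) subset_epochs(e, which(e$labels == "standard")))
  bind_eps <- function(lst) {
    arr <- do.call(abind_trials, lst)
    arr
  }
  train_decoder(bind_eps(tg), bind_eps(st), cfg, spatial, seed)
}

# row-bind epoch sets along the trial dimension
abind_trials <- function(...) {
  lst <- list(...)
  lst <- lst[vapply(lst, n_trials, integer(1)) > 0]
  assert_that(length(lst) > 0, "no trials to bind")
  d <- dim(lst[[1]]$epochs)
  nt <- sum(vapply(lst, n_trials, integer(1)))
  arr <- array(0, c(nt, d[2], d[3]))
  i <- 0L
  for (e in lst) {
    k <- n_trials(e)
    if (k > 0) arr[(i + 1):(i + k), , ] <- e$epochs
    i <- i + k
  }
  epoch_set(arr, lst[[1]]$fs, lst[[1]]$t0_offset,
            unlist(lapply(lst, `[[`, "labels")),
            lst[[1]]$channel_labels,
            do.call(rbind, lapply(lst, `[[`, "meta")))
}

decoder_score <- function(model, X) {
  Xz <- sweep(sweep(X, 2, model$scaler$mu), 2, model$scaler$sd, "/")
  as.numeric(Xz %*% model$w + model$b)
}

#' Classify one preprocessed epoch
#'
#' Applies the spatial filter, slope features and the linear scorer;
#' `detected` iff `score > theta` (strict: a score exactly at the threshold
#' is not a detection). A pure function of its inputs.
#'
#' @param model a `p300_decoder`.
#' @param epoch channels x samples matrix (25 Hz, 1 s) or a single-trial
#'   [epoch_set()].
#' @return list with `score` and `detected`.
#' @export
classify_epoch <- function(model, epoch) {
  if (is.matrix(epoch)) {
    assert_that(nrow(epoch) == length(model$spatial$channel_labels),
                "epoch has %d channels, model expects %d", nrow(epoch),
                length(model$spatial$channel_labels))
    epoch <- epoch_set(array(epoch, c(1, dim(epoch))), model$cfg$fs_dec, 0,
                       "target", model$spatial$channel_labels)
  }
  X <- slope_features(apply_spatial_filter(model$spatial, epoch), model$cfg)
  s <- decoder_score(model, X)
  list(score = s[1], detected = s[1] > model$theta)
}

#' @export
predict.p300_decoder <- function(object, newdata, ...) {
  X <- slope_features(apply_spatial_filter(object$spatial, newdata), object$cfg)
  s <- decoder_score(object, X)
  data.frame(score = s, detected = s > object$theta,
             message_id = if ("message_id" %in% names(newdata$meta))
               newdata$meta$message_id else NA_integer_)
}

#' @export
print.p300_decoder <- function(x, ...) {
  cat(sprintf("<p300_decoder> %d features, C = %g, theta = %.4f\n",
              length(x$w), x$C, x$theta))
  cat(sprintf("  trained on %d targets / %d standards; training bACC %.3f (AUC %.3f)\n",
              x$n_targets, x$n_standards, x$train_metrics$bACC,
              x$train_metrics$AUC))
  invisible(x)
}

#' @export
summary.p300_decoder <- function(object, ...) {
  cat("Single-trial P300 decoder\n")
  print(object)
  cat("  complexity grid (mean CV bACC):\n")
  print(object$cv, row.names = FALSE)
  cat(sprintf("  spatial filter: %d of %d xDAWN components\n",
              object$spatial$n_selected, ncol(object$spatial$W)))
  invisible(object)
}

#' @export
coef.p300_decoder <- function(object, ...) {
  stats::setNames(object$w, names(object$scaler$mu))
}

#' Serialize / restore a decoder as JSON
#'
#' Text round-trip of the full model (spatial filter, scaler, weights,
#' threshold, complexity).
#'
#' @param model a `p300_decoder`.
#' @param path file path.
#' @return `save_decoder`: the path invisibly; `load_decoder`: the model.
#' @export
save_decoder <- function(model, path) {
  obj <- list(
    spatial = list(W = model$spatial$W, A = model$spatial$A,
                   ratios = model$spatial$ratios,
                   n_selected = model$spatial$n_selected,
                   fs = model$spatial$fs,
                   channel_labels = model$spatial$channel_labels),
    cfg = unclass(model$cfg), scaler = model$scaler,
    w = model$w, b = model$b, C = model$C, theta = model$theta,
    n_targets = model$n_targets, n_standards = model$n_standards)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spatial <- structure(list(W = as.matrix(obj$spatial$W),
                            A = as.matrix(obj$spatial$A),
                            ratios = obj$spatial$ratios,
                            n_selected = obj$spatial$n_selected,
                            fs = obj$spatial$fs,
                            channel_labels = obj$spatial$channel_labels),
                       class = "xdawn_filter")
  cfg <- do.call(pipeline_config, obj$cfg)
  structure(list(spatial = spatial, cfg = cfg, scaler = obj$scaler,
                 w = obj$w, b = obj$b, C = obj$C, theta = obj$theta,
                 n_targets = obj$n_targets, n_standards = obj$n_standards,
                 cv = NULL, train_metrics = NULL),
            class = "p300_decoder")
}
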