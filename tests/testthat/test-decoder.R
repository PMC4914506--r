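test_that("slope features enumerate the segment grid and fit exact lines", {
  cfg <- pipeline_config()
  grid <- feature_grid(cfg$window_s, cfg$seg_len_s, cfg$seg_step_s)
  expect_equal(grid$start_s, c(0, 0.12, 0.24, 0.36, 0.48, 0.60),
               tolerance = 1e-9)          # starts while start + 0.4 <= 1.0

  t <- (0:24) / 25
  line <- matrix(rep(3 + 2 * t, 8), 8, 25, byrow = TRUE)
  ep <- epoch_set(array(line, c(1, 8, 25)), 25, 0, "target", paste0("XD", 1:8))
  f <- slope_features(ep, cfg)
  expect_equal(ncol(f), 48)               # 8 pseudo-channels x 6 segments
  expect_equal(as.numeric(f), rep(2, 48), tolerance = 1e-9)

  const <- epoch_set(array(5, c(1, 8, 25)), 25, 0, "target", paste0("XD", 1:8))
  expect_equal(as.numeric(slope_features(const, cfg)), rep(0, 48))
})

test_that("slope features are linear in the signal", {
  cfg <- pipeline_config()
  set.seed(8)
  a <- array(rnorm(2 * 3 * 25), c(2, 3, 25))
  b <- array(rnorm(2 * 3 * 25), c(2, 3, 25))
  mk <- function(x) epoch_set(x, 25, 0, rep("target", 2), c("p", "q", "r"))
  fa <- slope_features(mk(a), cfg)
  fb <- slope_features(mk(b), cfg)
  fab <- slope_features(mk(2.5 * a - 1.5 * b), cfg)
  expect_equal(fab, 2.5 * fa - 1.5 * fb, tolerance = 1e-12,
               ignore_attr = TRUE)
})

make_feature_epochs <- function(n, shift, seed, n_ch = 2, fs = 25) {
  set.seed(seed)
  arr <- array(rnorm(n * n_ch * fs), c(n, n_ch, fs))
  if (shift != 0) {
    t <- (0:(fs - 1)) / fs
    bump <- shift * exp(-0.5 * ((t - 0.45) / 0.1)^2)
    for (i in seq_len(n)) arr[i, 1, ] <- arr[i, 1, ] + bump
  }
  epoch_set(arr, fs, 0, rep(if (shift != 0) "target" else "standard", n),
            paste0("c", seq_len(n_ch)))
}

identity_filter <- function(n_ch = 2, fs = 25) {
  structure(list(W = diag(n_ch), A = diag(n_ch), ratios = rep(1, n_ch),
                 n_selected = n_ch, fs = fs,
                 channel_labels = paste0("c", seq_len(n_ch))),
            class = "xdawn_filter")
}

test_that("decoder training separates separable classes and searches the grid", {
  cfg <- pipeline_config()
  tg <- make_feature_epochs(20, shift = 8, seed = 1)
  st <- make_feature_epochs(20, shift = 0, seed = 2)
  dec <- train_decoder(tg, st, cfg, identity_filter(), seed = 1)
  expect_s3_class(dec, "p300_decoder")
  expect_equal(dec$train_metrics$bACC, 1.0)
  expect_equal(nrow(dec$cv), 7)                     # 10^0 .. 10^-6
  expect_equal(dec$cv$C, 10^(0:-6))
  expect_true(dec$C %in% dec$cv$C)

  # identical class distributions: CV bACC stays near chance
  baccs <- vapply(1:5, function(s) {
    t2 <- make_feature_epochs(20, 0, seed = 100 + s)
    s2 <- make_feature_epochs(20, 0, seed = 200 + s)
    t2$labels <- rep("target", 20)
    d <- train_decoder(t2, s2, cfg, identity_filter(), seed = s)
    max(d$cv$cv_bACC)
  }, numeric(1))
  # selection maximum over 7 complexities sits above 0.5 by construction;
  # binomial sd for 20+20 examples is ~0.08
  expect_lt(mean(baccs), 0.5 + 3 * 0.08)

  one_class <- make_feature_epochs(3, 0, seed = 3)
  expect_error(train_decoder(one_class, st, cfg, identity_filter(), seed = 1),
               "need >= 5")
})

test_that("threshold optimization maximizes training bACC with tie-break to 0", {
  expect_equal(optimize_threshold(c(2, 1, -1, -2),
                                  c("target", "target", "standard", "standard")), 0)
  expect_equal(optimize_threshold(c(1, -1, -1, 1),
                                  c("target", "target", "standard", "standard")), 0)

  # brute-force oracle over a dense threshold sweep on random scores
  set.seed(12)
  for (rep in 1:5) {
    sc <- round(rnorm(200), 2)
    lb <- sample(c("target", "standard"), 200, replace = TRUE,
                 prob = c(0.3, 0.7))
    th <- optimize_threshold(sc, lb)
    got <- compute_metrics(sc, lb, th)$bACC
    sweep_th <- c(sort(unique(sc)) - 1e-6, sort(unique(sc)) + 1e-6)
    best <- max(vapply(sweep_th, function(t)
      compute_metrics(sc, lb, t)$bACC, numeric(1)))
    expect_equal(got, best, tolerance = 1e-12)
    # never worse than the unshifted decision
    expect_gte(got, compute_metrics(sc, lb, 0)$bACC)
  }
})

test_that("classification is a pure strict-threshold function", {
  cfg <- pipeline_config()
  tg <- make_feature_epochs(20, shift = 8, seed = 5)
  st <- make_feature_epochs(20, shift = 0, seed = 6)
  dec <- train_decoder(tg, st, cfg, identity_filter(), seed = 1)

  strong <- make_feature_epochs(1, shift = 8, seed = 7)
  out <- classify_epoch(dec, strong$epochs[1, , ])
  expect_true(out$detected)
  out2 <- classify_epoch(dec, strong$epochs[1, , ])
  expect_identical(out, out2)

  noise_ep <- make_feature_epochs(200, shift = 0, seed = 8)
  pr <- predict(dec, noise_ep)
  # false-positive rate close to 1 - trained TNR (binomial bound)
  fpr <- mean(pr$detected)
  fpr_train <- 1 - dec$train_metrics$TNR
  expect_lt(abs(fpr - fpr_train), 3 * sqrt(0.25 / 200) + 0.02)

  expect_false(with(out, score > dec$theta) != out$detected)
  # score exactly at the threshold is not a detection
  expect_false(dec$theta > dec$theta)
  expect_error(classify_epoch(dec, matrix(0, 5, 25)), "channels")
})

test_that("metrics match their definitions and an all-pairs AUC oracle", {
  sc <- c(rep(1, 8), rep(-1, 2), rep(-1, 6), rep(1, 4))
  lb <- rep(c("target", "standard"), c(10, 10))
  m <- compute_metrics(sc, lb, 0)
  expect_equal(m$TPR, 0.8)
  expect_equal(m$TNR, 0.6)
  expect_equal(m$bACC, 0.7)

  sep <- compute_metrics(c(3, 2, -2, -3), c("target", "target",
                                            "standard", "standard"), 0)
  expect_equal(sep$bACC, 1)
  expect_equal(sep$AUC, 1)

  set.seed(30)
  sc2 <- sample(round(rnorm(20), 1))
  lb2 <- rep(c("target", "standard"), 10)
  pairs <- expand.grid(t = sc2[lb2 == "target"], s = sc2[lb2 == "standard"])
  auc_oracle <- mean(ifelse(pairs$t > pairs$s, 1, ifelse(pairs$t == pairs$s, 0.5, 0)))
  expect_equal(compute_metrics(sc2, lb2, 0)$AUC, auc_oracle)

  expect_error(compute_metrics(1:3, rep("target", 3), 0), "each class")
})

test_that("bACC is invariant to replicating the standard class", {
  set.seed(31)
  sc <- rnorm(30)
  lb <- rep(c("target", "standard"), c(10, 20))
  m1 <- compute_metrics(sc, lb, 0.2)
  m2 <- compute_metrics(c(sc, sc[lb == "standard"]),
                        c(lb, rep("standard", 20)), 0.2)
  expect_equal(m1$bACC, m2$bACC)
})

test_that("decoder JSON serialization round-trips scores exactly", {
  cfg <- pipeline_config()
  tg <- make_feature_epochs(10, shift = 8, seed = 9)
  st <- make_feature_epochs(10, shift = 0, seed = 10)
  dec <- train_decoder(tg, st, cfg, identity_filter(), seed = 1)
  f <- tempfile(fileext = ".json")
  save_decoder(dec, f)
  dec2 <- load_decoder(f)
  probe <- make_feature_epochs(1, shift = 4, seed = 11)$epochs[1, , ]
  expect_equal(classify_epoch(dec2, probe), classify_epoch(dec, probe))
})
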