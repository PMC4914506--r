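test_that("ERP averaging reduces noise at the CLT rate and rejects empty selections", {
  n <- 10
  arr <- array(0, c(n, 2, 30))
  for (i in 1:n) arr[i, , ] <- matrix(c(1:30, 30:1), 2, 30, byrow = TRUE)
  ep <- epoch_set(arr, 25, 0, rep("target", n), c("Pz", "Cz"))
  avg <- average_erp(ep)
  expect_equal(avg$mean[1, ], as.numeric(1:30))  # identical trials -> the trial
  expect_equal(avg$n_trials, n)
  expect_error(average_erp(ep, integer(0)), "empty")

  set.seed(44)
  n2 <- 500
  sigma <- 3
  tmpl <- 5 * exp(-0.5 * (((0:29) / 25 - 0.45) / 0.1)^2)
  arr2 <- array(rnorm(n2 * 1 * 30, sd = sigma), c(n2, 1, 30))
  for (i in 1:n2) arr2[i, 1, ] <- arr2[i, 1, ] + tmpl
  ep2 <- epoch_set(arr2, 25, 0, rep("target", n2), "Pz")
  avg2 <- average_erp(ep2)
  rmse <- sqrt(mean((avg2$mean[1, ] - tmpl)^2))
  expect_lt(rmse, 3 * sigma / sqrt(n2))
})

test_that("peak detection finds the positive maximum with earliest-tie-break", {
  fs <- 100
  t <- seq(-0.1, 1.0 - 1 / fs, by = 1 / fs)
  bump <- 5 * exp(-0.5 * ((t - 0.45) / 0.08)^2)
  avg <- structure(list(mean = matrix(bump, 1), fs = fs, t0_offset = -0.1,
                        n_trials = 1, condition = "toy",
                        channel_labels = "Pz"), class = "erp_average")
  pk <- detect_peak(avg, "Pz", c(0.3, 0.7))
  expect_equal(pk$latency, 0.45, tolerance = 1 / fs)
  expect_equal(pk$amplitude, 5, tolerance = 1e-3)

  ramp <- avg; ramp$mean <- matrix(t, 1)  # monotone rising: peak at window end
  pk2 <- detect_peak(ramp, "Pz", c(0.3, 0.7))
  expect_equal(pk2$latency, 0.7, tolerance = 1 / fs)

  two <- avg
  y <- numeric(length(t))
  y[which.min(abs(t - 0.35))] <- 2
  y[which.min(abs(t - 0.55))] <- 2
  two$mean <- matrix(y, 1)
  expect_equal(detect_peak(two, "Pz", c(0.3, 0.7))$latency, 0.35,
               tolerance = 1 / fs)
})

test_that("ISI grouping splits at the median with ties going short", {
  mk <- function(isis) epoch_set(array(0, c(length(isis), 1, 10)), 25, 0,
                                 rep("target", length(isis)), "Pz",
                                 meta = data.frame(preceding_isi = isis))
  g <- group_trials_by_isi(mk(c(5, 10, 15, 20)))
  expect_equal(g$short, c(1, 2))
  expect_equal(g$long, c(3, 4))
  expect_false(g$degenerate)

  g2 <- group_trials_by_isi(mk(c(15, 15, 15)))
  expect_true(g2$degenerate)

  g3 <- group_trials_by_isi(mk(c(5, 5, 25)))
  expect_equal(g3$short, c(1, 2))  # median 5; ties at the median go short
  expect_equal(g3$long, 3)
})

test_that("behavioral summary computes runtime, median RT, late and missed counts", {
  log <- toy_message_log(seq(0, by = 10, length.out = 30), rep(2, 30))
  bs <- behavioral_summary(log, pipeline_config())
  expect_equal(bs$total_runtime, 290)
  expect_equal(bs$median_rt, 2)
  expect_equal(bs$n_late, 0)
  expect_equal(bs$n_missed, 0)
  expect_equal(bs$mean_isi, 10 - 1.1)

  log2 <- toy_message_log(c(0, 30, 60), c(2, 3, 10))
  expect_equal(behavioral_summary(log2, pipeline_config())$median_rt, 3)

  log3 <- toy_message_log(c(0, 30, 60), c(14, 16, NA))
  bs3 <- behavioral_summary(log3, pipeline_config())
  expect_equal(bs3$n_late, 1)
  expect_equal(bs3$n_missed, 1)
  expect_true(bs3$runtime_truncated)
  # partition: answered (on-time + late) + missed = all first messages
  expect_equal(bs3$n_answered + bs3$n_missed, bs3$n_first)
  expect_equal((bs3$n_answered - bs3$n_late) + bs3$n_late + bs3$n_missed, 3)

  no_resp <- toy_message_log(c(0, 30), c(NA, NA))
  expect_error(behavioral_summary(no_resp, pipeline_config()), "median undefined")
})

test_that("grouped averages reproduce the simulator's engagement monotonicity", {
  cfg <- small_cfg()
  sim <- small_sim(engagement_gain = function(dt) ifelse(dt >= 12, 1, 0.15),
                   noise_white_sd = 1, noise_pink_sd = 1)
  op <- prompt_operator(3)
  sess <- simulate_session(sim, op, cfg, "adaptive",
                           decoder = oracle_decoder(0.5), n_messages = 24,
                           seed = 19)
  rec <- rereference_car(bandpass_erp(sess$recording, cfg$erp_band))
  ep <- extract_erp_epochs(rec, sess$events, cfg)
  kept <- reject_artifacts(ep, cfg$artifact_abs_uv)$kept
  g <- group_trials_by_isi(kept)
  expect_false(g$degenerate)
  pk_s <- detect_peak(average_erp(kept, g$short, "short"), "Pz", cfg$peak_window)
  pk_l <- detect_peak(average_erp(kept, g$long, "long"), "Pz", cfg$peak_window)
  expect_gt(pk_l$amplitude, pk_s$amplitude)
})

test_that("transfer evaluation trains on named runs and scores the test run", {
  cfg <- small_cfg()
  sim <- small_sim(engagement_gain = function(dt) rep(1, length(dt)))
  op <- prompt_operator(3)
  mk <- function(seed) {
    s <- simulate_session(sim, op, cfg, "fixed", nominal = 15,
                          n_messages = 15, seed = seed)
    list(recording = s$recording, events = s$events)
  }
  runs <- list(run1 = mk(301), run2 = mk(302), run5 = mk(303))
  designs <- data.frame(design = c("baseline", "transfer"),
                        train = c("run1", "run1+run2"),
                        test = c("run2", "run5"))
  tab <- transfer_evaluation(runs, designs, cfg, seed = 1)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$bACC >= 0 & tab$bACC <= 1))
  # identically-generated sessions at high SNR transfer without collapse
  expect_gt(min(tab$bACC), 0.8)

  bad <- data.frame(design = "x", train = "run1", test = "nope")
  expect_error(transfer_evaluation(runs, bad, cfg), "missing run")
  expect_error(transfer_evaluation(runs, designs[0, ], cfg), "empty design")
})

test_that("paired tests match hand-computed Friedman/Wilcoxon/Spearman results", {
  # 4 subjects x 3 conditions, condition C uniformly largest
  vals <- cbind(A = c(1, 2, 1.5, 2.2), B = c(2.1, 3, 2.5, 3.2),
                C = c(5, 6, 5.5, 6.2))
  res <- paired_condition_tests(vals)
  # hand-ranked oracle: within-subject ranks are (1,2,3) everywhere;
  # chi2_F = 12 n /(k(k+1)) * sum (Rbar_j - (k+1)/2)^2 = 4*2 = 8
  expect_equal(res$friedman$statistic, 8)
  expect_equal(res$friedman$df, 2)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(diff(res$pairwise$p_holm[order(res$pairwise$p)]) >= -1e-12))

  same <- cbind(A = 1:4, B = 1:4)
  res2 <- paired_condition_tests(same)
  expect_true(res2$pairwise$degenerate[1])
  expect_true(is.na(res2$pairwise$p[1]))

  expect_equal(rank_correlation(1:6, c(2, 4, 5, 7, 9, 20))$rho, 1)
  expect_error(rank_correlation(1, 1), "length >= 2")
})
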