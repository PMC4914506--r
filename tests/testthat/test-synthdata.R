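test_that("noise generator is silent at zero sd and reproducible from seed", {
  sim0 <- simulation_config(n_channels = 3, fs_raw = 200, noise_white_sd = 0,
                            noise_pink_sd = 0)
  rec <- generate_noise(sim0, 2)
  expect_true(all(rec$data == 0))
  expect_equal(dim(rec$data), c(3, 400))

  sim <- small_sim(n_channels = 4, fs_raw = 200)
  expect_identical(generate_noise(sim, 3, seed = 9)$data,
                   generate_noise(sim, 3, seed = 9)$data)
  expect_false(identical(generate_noise(sim, 3, seed = 9)$data,
                         generate_noise(sim, 3, seed = 10)$data))
  expect_error(generate_noise(sim, 0), "duration")
})

test_that("pink-only noise has a log-PSD slope near -1", {
  sim <- simulation_config(n_channels = 1, fs_raw = 1000, noise_white_sd = 0,
                           noise_pink_sd = 1)
  rec <- generate_noise(sim, 40, seed = 3)
  # smoothed-periodogram oracle on the generated signal
  sp <- spec.pgram(ts(rec$data[1, ], frequency = 1000), spans = 31,
                   plot = FALSE, taper = 0.1)
  keep <- sp$freq >= 1 & sp$freq <= 100
  slope <- coef(lm(log10(sp$spec[keep]) ~ log10(sp$freq[keep])))[2]
  expect_gt(slope, -1.25)
  expect_lt(slope, -0.75)
})

test_that("ERP injection adds the scaled template at the right time and place", {
  sim <- simulation_config(n_channels = 16, fs_raw = 100, noise_white_sd = 0,
                           noise_pink_sd = 0, artifact_rate = 0)
  zero <- generate_noise(sim, 10)
  log <- toy_message_log(3, 2)
  inj <- inject_erp(zero, log, sim)
  tmpl <- erp_template(sim, 100)
  pz <- which(zero$channel_labels == "Pz")
  got <- inj$recording$data[pz, 301:400]
  expect_equal(got, sim$erp_amp_uv * tmpl, tolerance = 1e-12)
  expect_true(all(inj$recording$data[, 1:300] == 0))
  expect_equal(inj$truth$amplitude, 1)  # g(Inf) = 1

  # linearity: two overlapping events superpose additively
  log2 <- event_log(time_s = c(3, 3.5), kind = c("msg_first", "msg_first"),
                    message_id = 1:2)
  inj2 <- inject_erp(zero, log2, sim, amplitudes = c(1, 1))
  manual <- numeric(1000)
  manual[301:400] <- manual[301:400] + sim$erp_amp_uv * tmpl
  manual[351:450] <- manual[351:450] + sim$erp_amp_uv * tmpl
  expect_equal(inj2$recording$data[pz, ], manual, tolerance = 1e-12)

  # engagement rule: g(dt) = min(1, dt/20) gives amplitude ratio 0.25
  simg <- simulation_config(n_channels = 4, fs_raw = 100, noise_white_sd = 0,
                            noise_pink_sd = 0,
                            engagement_gain = function(dt) pmin(1, dt / 20))
  log3 <- event_log(time_s = c(1, 6, 36), kind = rep("msg_first", 3),
                    message_id = 1:3)
  zero4 <- generate_noise(simg, 40)
  inj3 <- inject_erp(zero4, log3, simg)
  expect_equal(inj3$truth$amplitude[2] / inj3$truth$amplitude[3], 0.25)

  expect_error(inject_erp(zero, toy_message_log(9.5, 2), sim),
               "beyond the recording")
})

test_that("spatial pattern peaks at Pz and truth amplitudes follow g monotonically", {
  sim <- small_sim()
  pat <- erp_spatial_pattern(sim)
  expect_equal(unname(pat["Pz"]), 1)
  expect_true(all(pat <= 1) && all(pat >= 0))

  # shorter dt never yields a larger multiplier
  onsets <- cumsum(c(1, runif(30, 5, 30)))
  log <- event_log(time_s = onsets, kind = rep("msg_first", 31),
                   message_id = seq_along(onsets))
  zero <- simulation_config(n_channels = 4, fs_raw = 50, noise_white_sd = 0,
                            noise_pink_sd = 0)
  rec <- generate_noise(zero, max(onsets) + 2)
  truth <- inject_erp(rec, log, zero)$truth
  ord <- order(truth$dt)
  expect_true(all(diff(truth$amplitude[ord]) >= 0))
})

test_that("epoch averaging over many injected events recovers the template", {
  n_ev <- 200
  sigma <- 2
  sim <- simulation_config(n_channels = 8, fs_raw = 50,
                           noise_white_sd = sigma, noise_pink_sd = 0,
                           artifact_rate = 0, seed = 5)
  onsets <- seq(2, by = 2, length.out = n_ev)
  log <- event_log(time_s = onsets, kind = rep("msg_first", n_ev),
                   message_id = seq_len(n_ev))
  rec <- generate_noise(sim, max(onsets) + 2, seed = 5)
  inj <- inject_erp(rec, log, sim, amplitudes = rep(1, n_ev))
  pz <- which(rec$channel_labels == "Pz")
  ep <- vapply(onsets, function(t0)
    inj$recording$data[pz, (t0 * 50 + 1):(t0 * 50 + 50)], numeric(50))
  avg <- rowMeans(ep)
  rmse <- sqrt(mean((avg - sim$erp_amp_uv * erp_template(sim, 50, 1))^2))
  expect_lt(rmse, 3 * sigma / sqrt(n_ev))
})

test_that("simulated operator follows its latency and miss models", {
  sched <- toy_message_log(seq(5, by = 20, length.out = 5), rep(NA, 5))
  op <- prompt_operator(latency = 2)
  out <- simulate_operator(op, sched)
  resp <- out[out$kind == "response", ]
  expect_equal(nrow(resp), 5)
  expect_equal(resp$time_s, seq(5, by = 20, length.out = 5) + 2)

  op_miss <- operator_model(p_miss = function(dt) rep(1, length(dt)))
  out2 <- simulate_operator(op_miss, sched)
  expect_equal(sum(out2$kind == "response"), 0)

  # binomial bound: miss fraction of p = 0.3 over 1000 messages
  n <- 1000
  sched_big <- toy_message_log(seq(5, by = 2, length.out = n), rep(NA, n))
  op3 <- operator_model(rt_sampler = function(k) rep(1, k),
                        p_miss = function(dt) rep(0.3, length(dt)))
  out3 <- simulate_operator(op3, sched_big, seed = 21)
  miss_frac <- 1 - sum(out3$kind == "response") / n
  expect_lt(abs(miss_frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("identical seeds give bit-identical sessions end to end", {
  sim <- small_sim(n_channels = 6)
  op <- operator_model()
  a <- simulate_session(sim, op, small_cfg(), "fixed", nominal = 15,
                        n_messages = 5, seed = 33)
  b <- simulate_session(sim, op, small_cfg(), "fixed", nominal = 15,
                        n_messages = 5, seed = 33)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  expect_identical(a$truth, b$truth)
})
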