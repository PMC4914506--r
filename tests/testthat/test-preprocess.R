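test_that("DC removal centers constants, preserves zero, passes 10 Hz", {
  fs <- 500
  const <- eeg_recording(matrix(5, 1, 10 * fs), fs, "Cz")
  out <- dc_remove(const, 2)
  # step response of the high-pass decays with the time constant
  expect_lt(abs(out$data[1, 5 * fs]), 5 * exp(-2.4))
  expect_lt(abs(out$data[1, 10 * fs]), 0.05)

  zero <- eeg_recording(matrix(0, 2, 1000), fs, c("a", "b"))
  expect_equal(dc_remove(zero, 1)$data, zero$data)

  sine <- sine_recording(10, fs = fs, dur = 10)
  filt <- dc_remove(sine, 2)
  amp <- tone_amplitude(filt$data[1, (2 * fs):(10 * fs)], fs, 10)
  expect_gt(amp, 0.99)
  expect_lt(amp, 1.01)
})

test_that("decimation has the right length, passband and stopband", {
  fs <- 1000
  rec <- sine_recording(c(1, 10), fs = fs, dur = 60)
  dec <- decimate_recording(rec, 25, 4)
  expect_equal(ncol(dec$data), 1500)
  expect_equal(dec$fs, 25)
  mid <- 201:1300  # avoid filter edges
  expect_lt(abs(tone_amplitude(dec$data[1, mid], 25, 1) - 1), 0.05)
  expect_lt(max(abs(dec$data[2, mid])), 0.05)

  expect_error(decimate_recording(rec, 30, 4), "divide")
  expect_error(decimate_recording(rec, 25, 20), "Nyquist")
})

test_that("ERP band-pass passes 1 Hz, stops 50 Hz, and is zero phase", {
  fs <- 500
  rec <- sine_recording(c(1, 50), fs = fs, dur = 20)
  out <- bandpass_erp(rec, c(0.1, 30))
  mid <- (5 * fs):(15 * fs)
  expect_lt(abs(tone_amplitude(out$data[1, mid], fs, 1) - 1), 0.05)
  expect_lt(tone_amplitude(out$data[2, mid], fs, 50), 0.1)

  # zero phase: impulse response symmetric about the impulse (away from edges)
  imp <- matrix(0, 1, 40 * fs); imp[1, 20 * fs] <- 1
  ir <- bandpass_erp(eeg_recording(imp, fs, "Cz"), c(0.1, 30))$data[1, ]
  k <- 20 * fs
  w <- 100
  asym <- max(abs(ir[(k - w):(k - 1)] - rev(ir[(k + 1):(k + w)])))
  expect_lt(asym / max(abs(ir)), 1e-4)

  expect_error(bandpass_erp(rec, c(30, 0.1)), "low < high")
})

test_that("preprocessing is linear in the input amplitude", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(2 * 4000), 2, 4000), 200, c("a", "b"))
  chain <- function(r) decimate_recording(dc_remove(r, 2), 25, 4)
  scaled <- rec; scaled$data <- 3.7 * rec$data
  expect_equal(chain(scaled)$data, 3.7 * chain(rec)$data, tolerance = 1e-12)
})

test_that("CAR reconstructs the reference and zeroes every column sum", {
  x <- matrix(c(1, -1, 2, -2, 0.5, -0.5), 2, 3)
  rec <- eeg_recording(x, 100, c("C3", "C4"), "FCz")
  out <- rereference_car(rec)
  expect_equal(nrow(out$data), 3)
  expect_equal(out$channel_labels[3], "FCz")
  expect_lt(max(abs(colSums(out$data))), 1e-9)

  # pure CAR map (no reconstruction): all-equal channels vanish and a
  # common offset is removed exactly
  same <- eeg_recording(matrix(2, 3, 5), 100, c("a", "b", "c"), "FCz")
  expect_true(all(abs(rereference_car(same, add_reference = FALSE)$data) < 1e-12))

  set.seed(2)
  r5 <- eeg_recording(matrix(rnorm(50), 5, 10), 100, paste0("c", 1:5), "FCz")
  expect_lt(max(abs(colSums(rereference_car(r5)$data))), 1e-9)
  r5b <- r5; r5b$data <- r5$data + 42
  expect_equal(rereference_car(r5b, add_reference = FALSE)$data,
               rereference_car(r5, add_reference = FALSE)$data,
               tolerance = 1e-9)
})

test_that("training targets need an answered message within the latency cutoff", {
  fs <- 25
  rec <- eeg_recording(matrix(0, 1, 120 * fs), fs, "Pz")
  log <- toy_message_log(c(10, 40, 70), c(10, 14, 16))
  cfg <- pipeline_config()
  tr <- extract_classification_epochs(rec, log, cfg, "train")
  expect_equal(sum(tr$labels == "target"), 2)
  expect_equal(tr$meta$response_latency[tr$labels == "target"], c(10, 14))

  # boundary: latency exactly at the cutoff is included
  log15 <- toy_message_log(10, 15)
  tr15 <- extract_classification_epochs(
    eeg_recording(matrix(0, 1, 40 * fs), fs, "Pz"), log15, cfg, "train")
  expect_equal(sum(tr15$labels == "target"), 1)

  # online mode analyzes every first message, answered or not
  on <- extract_classification_epochs(rec, log, cfg, "online")
  expect_equal(nrow(on$meta), 3)
  expect_true(all(on$labels == "target"))
  log_miss <- toy_message_log(c(10, 40), c(NA, 3))
  on2 <- extract_classification_epochs(rec, log_miss, cfg, "online")
  expect_equal(sum(on2$labels == "target"), 2)
})

test_that("standards avoid task-relevant events per the exclusion envelope", {
  fs <- 25
  rec <- eeg_recording(matrix(0, 1, 10 * fs), fs, "Pz")
  log <- toy_message_log(5, 1.5)  # events at 5 (onset), 6.1 (offset), 6.5 (resp)
  cfg <- pipeline_config()
  tr <- extract_classification_epochs(rec, log, cfg, "train")
  got <- sort(tr$meta$onset[tr$labels == "standard"])

  # brute-force oracle: grid seconds whose [t-1, t+2] envelope avoids all events
  events <- c(5, 6.1, 6.5)
  want <- Filter(function(t0) !any(events >= t0 - 1 & events <= t0 + 2), 0:9)
  want <- want[want <= 10 - 1]  # window must fit the recording
  expect_equal(got, want)

  # train-mode targets and standards never overlap in time
  all_on <- tr$meta$onset
  ends <- all_on + 1
  ov <- outer(all_on, ends, function(a, b) a < b) &
    outer(ends, all_on, function(a, b) a > b)
  diag(ov) <- FALSE
  expect_false(any(ov))
})

test_that("ERP epochs are baseline corrected and need an answered message", {
  fs <- 100
  cfg <- pipeline_config()
  x <- matrix(7, 1, 30 * fs)  # constant offset channel
  rec <- eeg_recording(x, fs, "Pz")
  log <- toy_message_log(c(5, 15), c(2, NA))
  ep <- extract_erp_epochs(rec, log, cfg)
  expect_equal(n_trials(ep), 1)          # unanswered message dropped
  expect_equal(dim(ep$epochs)[3], round(1.1 * fs))
  expect_true(all(abs(ep$epochs) < 1e-12))  # constant removed by baseline
  expect_equal(ep$t0_offset, -0.1)
})

test_that("artifact rejection uses a strict +-100 uV boundary", {
  arr <- array(0, c(4, 1, 25))
  arr[1, 1, 10] <- 150; arr[2, 1, 10] <- 100; arr[3, 1, 10] <- -100.5
  ep <- epoch_set(arr, 25, 0, rep("target", 4), "Pz")
  res <- reject_artifacts(ep, 100)
  expect_equal(res$rejected, c(1, 3))
  expect_equal(n_trials(res$kept), 2)
  zero <- epoch_set(array(0, c(3, 1, 25)), 25, 0, rep("target", 3), "Pz")
  expect_equal(length(reject_artifacts(zero, 100)$rejected), 0)
})
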