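# Synthetic EEG generator: 1/f + white background noise, a parameterized
# parietal positive ERP whose amplitude is attenuated by ongoing task
# engagement, and boxcar artifacts. All randomness is reproducible from seeds.

# Schematic 2-D electrode coordinates for the extended 10-20 layout used by a
# 64-channel cap referenced at FCz. Coordinates are on an abstract grid
# (x: left negative / right positive, y: front positive / back negative);
# only relative distances matter, for the raised-cosine spatial pattern.
ten_twenty_positions <- function() {
  rows <- c(Fp = 4.5, AF = 3.6, F = 2.7, FT = 1.8, FC = 1.8, T = 0, C = 0,
            TP = -1.8, CP = -1.8, P = -2.7, PO = -3.6, O = -4.5, I = -5)
  labels <- c("Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8",
              "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
              "FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10",
              "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
              "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
              "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
              "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10",
              "O1", "Oz", "O2")
  parse1 <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
    row <- m[2]; pos <- m[3]
    y <- rows[[row]]
    if (pos == "z") x <- 0 else {
      k <- as.integer(pos)
      side <- if (k %% 2 == 1) -1 else 1       # odd left, even right
      x <- side * (ceiling(k / 2)) * 0.9
    }
    c(x = x, y = y)
  }
  xy <- t(vapply(labels, parse1, numeric(2)))
  data.frame(label = labels, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}

#' Electrode layout for the simulator
#'
#' Returns `n_channels` labels with schematic 2-D positions drawn from an
#' extended 10-20 64-channel montage (FCz is the recording reference and not
#' included). For fewer than 64 channels an evenly spread subset is taken,
#' always including Pz (the spatial maximum of the simulated ERP).
#'
#' @param n_channels number of channels (<= 64).
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
electrode_layout <- function(n_channels = 64) {
  full <- ten_twenty_positions()
  assert_that(n_channels >= 1 && n_channels <= nrow(full),
              "n_channels must be in 1..%d", nrow(full))
  if (n_channels == nrow(full)) return(full)
  idx <- unique(round(seq(1, nrow(full), length.out = n_channels)))
  while (length(idx) < n_channels) idx <- unique(c(idx, setdiff(seq_len(nrow(full)), idx)[1]))
  sel <- full[sort(idx[seq_len(n_channels)]), , drop = FALSE]
  if (!"Pz" %in% sel$label) {
    pz <- full[full$label == "Pz", , drop = FALSE]
    # replace the nearest selected electrode by Pz
    d <- (sel$x - pz$x)^2 + (sel$y - pz$y)^2
    sel[which.min(d), ] <- pz
  }
  rownames(sel) <- NULL
  sel
}

#' Simulation configuration
#'
#' Parameters of the synthetic-EEG generator. Defaults emulate the recording
#' setup the pipeline is designed for: 64 channels referenced at FCz, sampled
#' at 5 kHz, with 1/f ("pink") plus white background noise, rare task-message
#' events evoking a parietal positive deflection peaking 450 ms
#' post-stimulus, and occasional high-amplitude boxcar artifacts. The
#' engagement gain `g(dt)` maps the time since the previous first task
#' message (s) to an ERP amplitude multiplier in (0, 1]; it is non-increasing
#' toward short intervals so that rapid message sequences attenuate the
#' simulated P300. Default `g(dt) = clip(dt / 20, 0.3, 1)`.
#'
#' @param n_channels number of EEG channels (default 64).
#' @param fs_raw sampling rate in Hz (default 5000).
#' @param noise_white_sd white-noise standard deviation, uV.
#' @param noise_pink_sd 1/f-noise standard deviation, uV.
#' @param erp_peak_s template peak latency after stimulus onset, s.
#' @param erp_width_s template Gaussian standard deviation, s.
#' @param erp_amp_uv base peak amplitude at the pattern maximum (Pz), uV.
#' @param engagement_gain function `dt -> multiplier in (0,1]`, non-increasing.
#' @param artifact_rate artifacts per minute.
#' @param artifact_amp_uv artifact boxcar amplitude, uV.
#' @param artifact_dur_s artifact duration, s.
#' @param pattern_radius raised-cosine radius of the spatial pattern, grid units.
#' @param seed RNG seed used by generator functions unless overridden.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_channels = 64, fs_raw = 5000,
                              noise_white_sd = 4, noise_pink_sd = 4,
                              erp_peak_s = 0.45, erp_width_s = 0.08,
                              erp_amp_uv = 8,
                              engagement_gain = function(dt) clip(dt / 20, 0.3, 1),
                              artifact_rate = 1, artifact_amp_uv = 150,
                              artifact_dur_s = 0.5,
                              pattern_radius = 3.2, seed = 1L) {
  assert_that(noise_white_sd >= 0 && noise_pink_sd >= 0, "noise sds must be >= 0")
  assert_that(is.function(engagement_gain), "engagement_gain must be a function")
  layout <- electrode_layout(n_channels)
  structure(list(n_channels = n_channels, fs_raw = fs_raw,
                 noise_white_sd = noise_white_sd, noise_pink_sd = noise_pink_sd,
                 erp_peak_s = erp_peak_s, erp_width_s = erp_width_s,
                 erp_amp_uv = erp_amp_uv, engagement_gain = engagement_gain,
                 artifact_rate = artifact_rate,
                 artifact_amp_uv = artifact_amp_uv,
                 artifact_dur_s = artifact_dur_s,
                 pattern_radius = pattern_radius,
                 layout = layout, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Spatial pattern of the simulated ERP
#'
#' Raised cosine over the schematic layout, centered on Pz, maximum 1.
#'
#' @param sim a [simulation_config()].
#' @return numeric vector, one weight per channel.
#' @export
erp_spatial_pattern <- function(sim) {
  lay <- sim$layout
  ctr <- lay[lay$label == "Pz", ]
  d <- sqrt((lay$x - ctr$x)^2 + (lay$y - ctr$y)^2)
  w <- 0.5 * (1 + cos(pi * pmin(d / sim$pattern_radius, 1)))
  names(w) <- lay$label
  w
}

#' Temporal ERP template
#'
#' Gaussian bump over `[0, 1)` s after stimulus onset, unit peak amplitude.
#'
#' @param sim a [simulation_config()].
#' @param fs sampling rate of the signal the template is injected into.
#' @param duration_s template support length, s.
#' @return numeric vector of `round(duration_s * fs)` samples.
#' @export
erp_template <- function(sim, fs, duration_s = 1) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  exp(-0.5 * ((t - sim$erp_peak_s) / sim$erp_width_s)^2)
}

# one channel of 1/f-amplitude noise via spectral shaping, unit sd
pink_noise_1 <- function(n) {
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(spec[nf]))  # Nyquist bin must be real
    if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[n:(n - nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate background EEG noise
#'
#' Pink (1/f amplitude-spectrum) plus white Gaussian noise, per channel,
#' reproducible from the seed.
#'
#' @param sim a [simulation_config()].
#' @param duration_s recording length in seconds (> 0).
#' @param seed RNG seed; defaults to `sim$seed`.
#' @return an [eeg_recording()].
#' @export
generate_noise <- function(sim, duration_s, seed = sim$seed) {
  assert_that(duration_s > 0, "duration must be > 0")
  n <- round(duration_s * sim$fs_raw)
  nc <- sim$n_channels
  with_seed(seed, {
    x <- matrix(0, nc, n)
    if (sim$noise_pink_sd > 0)
      for (i in seq_len(nc)) x[i, ] <- sim$noise_pink_sd * pink_noise_1(n)
    if (sim$noise_white_sd > 0)
      x <- x + matrix(stats::rnorm(nc * n, sd = sim$noise_white_sd), nc, n)
    eeg_recording(x, sim$fs_raw, sim$layout$label, "FCz")
  })
}

#' Inject stimulus-locked ERPs into a recording
#'
#' For every `msg_first` event at time `t`, adds
#' `pattern %o% (a * template)` aligned at `t`, where
#' `a = erp_amp_uv * g(dt)` and `dt` is the time since the previous
#' `msg_first` onset (the first message gets `g(Inf) -> 1`). Overlapping
#' responses superpose additively. Events whose per-event `amplitude` is
#' supplied (e.g. 0 for a missed message) override the engagement rule.
#'
#' @param rec an [eeg_recording()] (raw sampling rate).
#' @param events an [event_log()].
#' @param sim a [simulation_config()].
#' @param amplitudes optional numeric vector, one multiplier per `msg_first`
#'   event, overriding `engagement_gain`.
#' @return list with `recording` (signal added) and `truth`, a data.frame of
#'   per-event ground truth (message id, onset, dt, amplitude multiplier).
#' @export
inject_erp <- function(rec, events, sim, amplitudes = NULL) {
  firsts <- events[events$kind == "msg_first", , drop = FALSE]
  tmpl <- erp_template(sim, rec$fs)
  pat <- erp_spatial_pattern(sim)
  assert_that(length(pat) == n_channels(rec),
              "simulation layout (%d ch) does not match recording (%d ch)",
              length(pat), n_channels(rec))
  L <- length(tmpl)
  n <- n_samples(rec)
  dts <- c(Inf, diff(firsts$time_s))
  mult <- if (is.null(amplitudes)) sim$engagement_gain(dts) else {
    assert_that(length(amplitudes) == nrow(firsts),
                "need one amplitude per msg_first event")
    amplitudes
  }
  x <- rec$data
  for (i in seq_len(nrow(firsts))) {
    s0 <- floor(firsts$time_s[i] * rec$fs) + 1
    assert_that(s0 + L - 1 <= n,
                "event at %.2f s extends beyond the recording", firsts$time_s[i])
    a <- sim$erp_amp_uv * mult[i]
    if (a != 0)
      x[, s0:(s0 + L - 1)] <- x[, s0:(s0 + L - 1)] + outer(pat, a * tmpl)
  }
  out <- rec
  out$data <- x
  list(recording = out,
       truth = data.frame(message_id = firsts$message_id,
                          onset = firsts$time_s, dt = dts,
                          amplitude = mult))
}

#' Inject boxcar artifacts
#'
#' Adds rectangular offsets of `+-artifact_amp_uv` and duration
#' `artifact_dur_s` at Poisson-distributed times (rate `artifact_rate` per
#' minute) on a random channel each, so that amplitude-based rejection is
#' exercised.
#'
#' @param rec an [eeg_recording()].
#' @param sim a [simulation_config()].
#' @param seed RNG seed; defaults to `sim$seed + 1`.
#' @return list with `recording` and `intervals` (data.frame of onset/offset/channel/sign).
#' @export
inject_artifacts <- function(rec, sim, seed = sim$seed + 1L) {
  dur <- rec_duration(rec)
  with_seed(seed, {
    k <- stats::rpois(1, sim$artifact_rate * dur / 60)
    if (k == 0)
      return(list(recording = rec,
                  intervals = data.frame(onset = numeric(), offset = numeric(),
                                         channel = integer(), sign = numeric())))
    onset <- sort(stats::runif(k, 0, dur - sim$artifact_dur_s))
    ch <- sample.int(n_channels(rec), k, replace = TRUE)
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    x <- rec$data
    for (i in seq_len(k)) {
      s0 <- floor(onset[i] * rec$fs) + 1
      s1 <- min(s0 + round(sim$artifact_dur_s * rec$fs) - 1, n_samples(rec))
      x[ch[i], s0:s1] <- x[ch[i], s0:s1] + sgn[i] * sim$artifact_amp_uv
    }
    out <- rec
    out$data <- x
    list(recording = out,
         intervals = data.frame(onset = onset,
                                offset = onset + sim$artifact_dur_s,
                                channel = ch, sign = sgn))
  })
}
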