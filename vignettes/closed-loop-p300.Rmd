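---
title: "Closed-loop adaptation of stimulus timing from single-trial P300 detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop adaptation of stimulus timing from single-trial P300 detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300loop)
```

## The problem

An operator supervising several semi-autonomous robots receives task
messages through a man-machine interface (MMI). Each recognized, rare,
task-relevant message evokes a P300 - a positive parietal EEG deflection
roughly 300-700 ms post-stimulus whose amplitude scales with the processing
resources the operator can allocate to the message. When the operator is
still engaged in a previous task (a short time since the last message), the
P300 to a new message is attenuated or absent. `p300loop` implements a
passive brain-computer interface built on this effect: a decoder detects
P300-related activity after every first task message in single trial, and a
controller uses the detection outcome to adapt the inter-stimulus interval
(ISI) of the message scheduler - messages come faster while the operator has
spare capacity and slower while they are loaded.

Because real recordings of this kind are not distributable, the package
carries a synthetic-EEG and operator simulator as a first-class module, so
every stage - from file I/O to the closed loop - is testable end to end.

## Processing chain

1. **Acquisition model.** 64 channels referenced at FCz, sampled at 5 kHz
   (`pipeline_config()` defaults; any rate with an integer factor to the
   25 Hz classification rate works).
2. **Online preprocessing.** Causal DC removal (first-order exponential
   high-pass, time constant 2 s - the constant only needs to be large
   against the 1 s analysis window and short against drift), then
   anti-alias decimation to 25 Hz. The FIR low-pass has its passband edge at
   4 Hz and its stopband edge at 10 Hz with >= 50 dB attenuation, so 10 Hz
   alpha activity cannot alias into the 12.5 Hz Nyquist band.
3. **Windowing.** 1 s windows after each first task message are targets;
   in training, only messages answered within 15 s qualify (boundary
   inclusive), and standards are cut on a 1 s grid whose `[-1, +1]` s
   envelope around the window contains no message or response event. In the
   online mode every first message is analyzed, answered or not.
4. **xDAWN spatial filtering.** The evoked response is estimated by least
   squares with a Toeplitz 0/1 design (correct under overlapping
   responses), and filters maximize the signal-to-signal-plus-noise ratio.
   We solve the generalized Rayleigh quotient by Cholesky whitening plus a
   symmetric eigendecomposition, which is algebraically equivalent to the
   QR/SVD formulation; the tests cross-check it against a dense generalized
   eigensolver. The top 8 pseudo-channels are retained.
5. **Features and classifier.** Ordinary least-squares line slopes over
   400 ms segments every 120 ms (six segments per 1 s window, 48 features),
   z-scored on the training data, feed a linear SVM. The complexity is
   selected from `10^0 ... 10^-6` by stratified five-fold cross-validated
   balanced accuracy; ties prefer the larger C. After the final fit the
   decision threshold is shifted to the value maximizing training balanced
   accuracy (candidates are midpoints between sorted unique scores; ties
   resolve toward zero). Detection is strict: `score > theta`.
6. **Controller.** ISI preset 25 s, bounds 5-35 s, step 5 s: two detected
   outcomes in a row lower the ISI one step, two not-detected outcomes
   raise it one step; the triggering streak then resets, so `2k` identical
   outcomes move `k` steps. Fixed-ISI runs use a nominal value (25 or 15 s)
   plus uniform +-5 s jitter; adaptive runs use the controller value with
   no jitter. The scheduler presents the head of a FIFO queue whenever the
   ISI has elapsed since the previous presentation *offset* (presentations
   last 1.1 s); a message unanswered 13 s after onset re-enters the queue
   as a repeat with elevated priority.
7. **ERP analysis (offline).** 0.1-30 Hz zero-phase band-pass, common
   average reference with reconstruction of FCz, epochs -0.1..1.0 s with
   pre-stimulus baseline correction, rejection of trials exceeding
   +-100 uV (strictly), positive-peak detection in 0.3-0.7 s, and a
   per-subject median split of adaptive-run trials into ISI-short/ISI-long
   groups.

## What the simulator emulates - and what it does not

`simulation_config()` generates 1/f-plus-white background noise, injects a
Gaussian-bump ERP (peak 0.45 s, sd 0.08 s, base amplitude 8 uV) with a
raised-cosine spatial pattern peaking at Pz, and adds boxcar artifacts of
+-150 uV x 0.5 s so the +-100 uV rejection stage is exercised. Engagement
enters through `g(dt)`, a non-increasing multiplier of the ERP amplitude in
the time `dt` since the previous first message. The default
`g(dt) = clip(dt/20, 0.3, 1)` is a deliberate stand-in - no quantitative
amplitude-versus-engagement law is established for this paradigm - chosen so
that gaps of 5-10 s visibly attenuate the response while gaps >= 20 s do
not. A missed message evokes nothing (`g = 0`), which is exactly why the
closed loop also responds to full misses.

The simulated operator answers each presentation of an unanswered message
with probability `1 - p_miss(dt)` at a lognormal latency (median 4 s,
sdlog 0.8, about 5% beyond the 15 s late bound), so late responses and
missed messages occur at realistic rates.

The simulator does **not** model biophysical head geometry, eye-blink or
EMG artifact morphology, oscillatory (alpha/beta) structure, or the
execution dynamics of the three robot task types (task type is metadata
only). Passing tests therefore demonstrate the correctness and the
qualitative closed-loop behavior of the pipeline, not expected performance
on recorded EEG.

## Numerical and design choices

* **Boundaries.** "Within 15 s" and "within 13 s" are inclusive;
  artifact rejection is strict (`> 100` uV rejects, `== 100` is kept);
  detection is strict (`score > theta`).
* **Time conventions.** Event times are seconds from recording start;
  windows are half-open `[t_on, t_off)`; the ISI is measured from
  presentation offset to the next onset, consistently in the scheduler and
  the analyses.
* **Scheduler termination.** Repeats per message are capped at two; after
  that an unanswered message counts as missed for good. The cap is a
  package choice (the repetition policy beyond "re-queue with elevated
  priority" is open in this paradigm) and guarantees termination under a
  silent operator.
* **Reference reconstruction.** `rereference_car()` appends the recording
  reference as a zero channel before averaging, so every output sample sums
  to zero across channels. The pure CAR map (no reconstruction) is
  available via `add_reference = FALSE`; only the pure form is invariant to
  a common offset across the input channels.
* **Degenerate inputs.** Rank-deficient covariances get a relative ridge
  (`1e-6 * trace/dim`) with a warning; all-equal preceding ISIs make the
  short/long split degenerate and are flagged rather than split; zero
  score variance cannot occur in the threshold search because guards beyond
  the extreme scores are always candidates.
* **Single-run training.** `fit_p300_decoder()` accepts several runs and
  concatenates them along time for the xDAWN fit; the evaluation designs
  that average over single-run trainings are expressed as rows of the
  design table of `transfer_evaluation()`.

## Problem sizes used in the test suite

The simulator's defaults mirror the full acquisition setup (64 channels at
5 kHz). The test and evaluation sessions in this package run a scaled-down
but structurally identical configuration - 16 channels at 100 Hz raw rate
(still an integer factor of 200/8 to 25 Hz), 30 messages per run - which the
package treats as its reference desk-scale experiment: the decimated 25 Hz
windows, and hence everything downstream of decimation, are identical in
shape to the full-scale case. With a template amplitude four times the
total background sd, held-out balanced accuracy on a third simulated
session exceeds 0.9 and decays to chance as the amplitude goes to zero; a
closed-loop run against an operator whose P300 attenuates below a 12 s
engagement gap settles between 10 and 15 s mean ISI and finishes in roughly
half the runtime of the fixed 25 s condition. Those checks are computed by
`tests/testthat/test-acceptance.R` - the vignette states no number the
suite does not itself produce.

## Known limitations

* The engagement law `g`, the reaction-time model and the artifact shape
  are simulator conventions, not estimates from data.
* The xDAWN fit assumes a stationary spatial pattern across the training
  runs; no online recalibration is provided.
* The online preprocessing warm-up (20 s of signal before each classified
  window) reproduces the batch filters only up to filter start-up
  transients; with the 2 s DC time constant and a sub-second FIR this
  difference is negligible, but very short warm-ups would not be.
* BrainVision support covers the two multiplexed binary dialects (16-bit
  integer, 32-bit float); vectorized/ASCII files and EDF/FIF are out of
  scope.
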