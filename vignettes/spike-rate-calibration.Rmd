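---
title: "Calibrating spike rate inference for calcium imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating spike rate inference for calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikecal)
```

# The problem

Calcium imaging reports neuronal spiking only indirectly: each action
potential (or burst) drives a slow fluorescence transient, corrupted by
shot noise and sampled at the imaging frame rate. Recovering a continuous
spike-rate trace from the dF/F signal therefore needs either a forward
model that can be inverted (deconvolution) or a supervised regressor
trained on paired recordings in which both the fluorescence and the true
spike times of the same neuron are known ("ground truth"). For spinal
cord dorsal horn neurons expressing GCaMP6s, such ground truth shows
calcium kernels that decay several-fold slower than in cortex (around
3-4 s), moderate burstiness, spike rates spanning an order of magnitude
across neurons, and strongly episodic firing.

`spikecal` implements the complete calibration loop around such data:

1. containers and I/O for paired recordings (`GroundTruthRecording`,
   `GroundTruthDataset`, a lossless JSON dialect, and a MAT-v5 importer
   for the deposited layout);
2. a synthetic ground-truth generator with the statistical structure of
   dorsal horn cohorts, so every downstream stage is testable without
   downloads;
3. standardized noise levels and resampling of recordings to target
   frame rates and noise levels;
4. calcium kernel extraction by regularized deconvolution with
   single-exponential fits;
5. three inference approaches: a supervised convolutional network with
   leave-one-out retraining, non-negative AR(1) deconvolution, and raw
   dF/F as a proxy;
6. the evaluation suite: shift-optimized correlations, false
   positive/negative curves, 5-s segment comparisons, high-frequency
   event analysis, and rate-variability summaries.

# Data model and units

dF/F is always in percent, times in seconds, rates in Hz. A
`RecordingSegment` pairs one `FluorescenceTrace` (dF/F, frame rate, t0)
with one `SpikeTrain` (sorted spike times, duration, optional stimulation
times) on a common clock; a neuron may contribute several segments (a
slow large-field-of-view acquisition and a fast zoomed one). dF/F is
computed from raw fluorescence as `100 * (F - F0) / F0` with F0 a global
percentile of the whole trace (default the 10th; linear interpolation
between order statistics). A global rather than running baseline is
appropriate for these short, drift-free recordings; the percentile
convention matters on short traces and is therefore fixed and documented.

# Standardized noise

The standardized noise level is

$$\nu = \mathrm{median}_t\,|\mathrm{dF/F}_{t+1} - \mathrm{dF/F}_t| \;/\; \sqrt{f_r},$$

in percent per sqrt(Hz), comparable across frame rates. For i.i.d.
Gaussian noise of per-sample SD $\sigma$,
$\nu = \sigma\sqrt2\,\Phi^{-1}(0.75)/\sqrt{f_r}$, which the tests verify
by Monte Carlo. Note that $\nu$ is measured on the full trace: for very
active neurons at slow frame rates the median frame-to-frame step is
dominated by the spiking signal itself, so $\nu$ has a signal floor. The
noise-injection routines treat a requested level as exact where
reachable (within 2%, one corrective iteration on an analytic first
guess) and, in cohort generation, as a floor otherwise — matching the
per-neuron spread of measured noise in recorded cohorts.

Resampling a recording to a target condition (e.g. 30 Hz, noise 7)
requires a source segment at least as fast and at most as noisy as the
target. Decimation averages consecutive frames for integer rate ratios
(mimicking longer dwell times) and uses a boxcar plus linear
interpolation otherwise; upsampling and noise removal are refused. Noise
is added after decimation by default (a flag flips the order; for
white noise the two are equivalent up to a sqrt-ratio rescaling).
Spikes are never resampled.

Ground-truth rate traces are built by convolving the discrete spikes
with a unit-area Gaussian whose SD is matched to the frame rate
(0.4 s at 2.5 Hz down to 0.05 s at 30 Hz, each intermediate rate using
the next-lower table entry; above 30 Hz, 0.05 s). The truth trace
integrates back to the spike count up to edge truncation.

# The synthetic cohort generator

The generator's defaults are the study conditions, chosen once:

* **Spike trains.** A tonic Poisson process (thinned by a 3 ms absolute
  refractory period, with the generation rate inflated so the mean rate
  is unbiased) superimposed with Poisson-seeded bursts of geometric size
  (mean 3, minimum 2) at 5 ms intra-burst intervals. `burstFraction`
  directly targets the fraction of spikes with a nearest neighbour
  within 10 ms, the burstiness statistic used throughout. Cohort presets
  additionally enable a slow two-state telegraph modulation of the whole
  process (rate ratio 3, mean dwell 15 s, long-run mean preserved):
  recorded dorsal horn neurons fire in episodes, and this
  non-stationarity is what makes spike rates discriminable between time
  segments of one neuron. In the bare `spikeGenConfig` the modulation is
  off, so the homogeneous-process identities (ISI CoV of 1 for a Poisson
  train, etc.) hold exactly.
* **Fluorescence.** Per spike, a transient with a 0.1 s linear rise
  (a nuisance parameter, unresolvable at slow sampling) and a
  single-exponential decay; superposition is evaluated exactly at frame
  times. An optional soft saturation `C * tanh(x / C)` models indicator
  saturation during high-frequency events; it is off by default.
  Gaussian noise is calibrated to the regime's standardized level.
* **Presets.** `glut_sc`: 21 neurons, per-neuron mean rates log-normal
  with median 3.7 Hz and log-SD 0.60 (interquartile ratio ~2.3), burst
  fraction 16%, kernel tau 3.1 s, amplitude set so the mean kernel
  response over the first 2 s is ~12% dF/F. `gaba_sc`: 23 neurons,
  median 1.1 Hz with log-SD 0.91, burst fraction 6.5%, tau 4.4 s, ~11%
  mean 2-s response. `cortex_like`: fast kernels (0.8 s) and heavy
  bursting (42%). Per-neuron kernel amplitudes are log-normal with CV
  0.6 (consistent with a median-to-SD ratio of roughly 12 to 6); the
  distributional form is a modeling choice, as only the spread is
  characterized empirically. Two acquisition regimes per neuron share
  one underlying spike train: 2.5 Hz at high noise and 30 Hz at noise
  1.0.
* **Observed baseline.** By default the generator re-extracts dF/F from
  the simulated fluorescence through the same global 10th-percentile
  baseline applied to recorded movies. For neurons that rarely return to
  rest the percentile overestimates F0, compressing that neuron's dF/F
  by a per-neuron affine factor. This leaves within-neuron structure
  (and per-neuron correlations) intact but degrades amplitude
  comparability across neurons — the property that makes across-neuron
  rate comparisons genuinely hard in recorded cohorts.

What the generator does **not** emulate: baseline drift and bleaching,
neuropil contamination, motion artifacts, non-Gaussian (shot) noise,
nonlinear supralinearity of few-spike responses, and biophysical
indicator kinetics. Passing tests on synthetic cohorts therefore
demonstrate the correctness and calibration of the pipeline under the
stated forward model, not performance on any particular real recording.

All randomness flows through R's Mersenne-Twister stream (one
`set.seed` per cohort; per-neuron noise seeds derived arithmetically),
and the network training uses its own mt19937/Box-Muller stream keyed by
the training seed, so results are reproducible across platforms.

# Kernel extraction

The calcium response to the average action potential is the kernel $k$
minimizing $\|X k - y\|^2 + \lambda\,\|L k\|^2$, where $X$ is the
convolution design built from frame-binned spike counts at a common
2.5 Hz rate, $y$ the dF/F trace, and $L$ a second-difference operator.
The window is [-2, +10] s; pre-spike samples are retained as a sanity
band that should sit near zero. $\lambda$ is selected by generalized
cross-validation over a 33-point logarithmic grid (with a tiny ridge for
numerical safety) and is reported in the result. The covariance of the
estimate is propagated through the solve.

The decay fit is least squares of $A\,e^{-t/\tau}$ on the post-peak
samples (the fit window starting at the peak is a package choice). Its
90% confidence interval is a 200-resample parametric bootstrap run
through the full estimator: each replicate redraws the trace noise at
the plug-in variance, re-selects $\lambda$ on a local grid, re-solves,
and refits; the interval is the basic (reflected) bootstrap interval,
which also corrects the first-order shrinkage bias of the regularizer.
Residual-resampling alternatives undercover badly here because
deconvolved-kernel errors are strongly autocorrelated. A simulation
calibration (in the test suite) checks that the interval covers the
generating tau at close to its nominal rate. Degenerate inputs are
explicit: an all-zero trace yields an all-zero kernel; fewer than 20
spikes, or a non-decaying kernel, raise errors.

The linear forward model is the convolution of the binned spikes with
the kernel (linearly interpolated between sampling rates); the linearity
analysis pairs its prediction with the observed dF/F at 3 Hz and reports
the product-moment correlation.

# Inference approaches

* **Supervised network.** Input: a window of dF/F samples symmetric
  around the inferred frame (64 samples, or 32 below 15 Hz); output: the
  smoothed true rate at the center. Three convolutional layers (filters
  31/19/5, or 17/9/3 below 15 Hz; 20/30/40 features), max pooling after
  the second and third, a 10-unit dense layer, ReLU activations, linear
  output clipped at zero. Training minimizes MSE with Adam
  (learning rate 2.5e-3, batch 128, up to 10 epochs, early stopping on a
  10% held-in split, at most 2500 windows subsampled per model) — CPU
  scale defaults, recorded in the model's provenance. Inputs are
  z-scored with training-set statistics. Edge frames without a full
  window are NA and excluded from metrics rather than zero-filled. A
  rare collapsed (constant-output) fit is detected on a training probe
  and retrained from a new initialization. Leave-one-out retraining
  trains one model per test neuron with that neuron excluded; the
  exclusion is recorded in the model and asserted by tests.
* **Non-negative deconvolution.** The unsupervised baseline solves
  $\min\|c - y\|^2$ subject to $s_t = c_t - \gamma c_{t-1} \ge 0$ with
  $\gamma = e^{-1/(f_r \tau)}$ via the online pool-merging algorithm
  (exactly equivalent to dense non-negative least squares, verified
  against an oracle in the tests; the leading pool is clipped at zero
  exactly as the KKT conditions require). Its output is in arbitrary
  units. The benchmark runs it at the stock decay constant of the widely
  used source-extraction toolboxes (1.0 s) — the baseline as
  practitioners run it out of the box, and deliberately mismatched to
  the ~3 s spinal kernels; an indicator-matched variant (dataset kernel
  tau) is available via `decayTau = "kernel"`.
* **Raw dF/F.** The identity, tagged so that evaluation applies the
  same shift and smoothing optimization as for the deconvolution
  baseline.

# Evaluation

Correlations are product-moment throughout. For each dataset and method
a single temporal shift (grid step one frame, range ±1 s) maximizing the
mean correlation across neurons is chosen; for the two uncalibrated
baselines a Gaussian evaluation smoothing SD is jointly grid-searched
(0 to 2 s) at the dataset level. False positive/negative curves bin the
absolute inferred rate (calibrated method only) and the true spikes into
windows from 0.5 s up to the recording duration; at the full duration
the signed difference is the overall rate bias, and FP+FN is bounded
below by its magnitude at every window. Segment comparisons split
recordings into 5 s segments and score sign agreement of inferred versus
true count differences; truth ties are excluded, inference ties get half
credit (a package choice), within-neuron comparisons enumerate all
segment pairs, across-neuron comparisons enumerate ordered neuron pairs
(matching the convention of reporting 2·C(n,2) pairs) with an optional
per-pair sampling cap. True segment counts always come from raw spike
times, never from smoothed rates. No multiple-testing correction is
applied to the per-cell paired signed-rank tests; raw p-values are
reported.

High-frequency events are episodes where the instantaneous ground-truth
rate exceeds 45 Hz; the instantaneous rate is operationalized as the
reciprocal inter-spike interval assigned to each gap (a smoothed-rate
strategy is available as an alternative), events merge within 1 s so the
1 s counting windows never overlap, and event-triggered averages drop
events whose display window does not fit in the trace, with a logged
count. The stimulation-exclusion window for spontaneous-only statistics
defaults to 2 s.

# Problem sizes and budgets

The test-suite and acceptance-script defaults are sized for a single
CPU: cohorts of 8 neurons at 120 s per regime for the benchmark
condition (30 Hz, standardized noise 7), 200 simulations for the
kernel-CI calibration, 10 seeds for the paired method comparisons, and
2500-window network trainings. These sizes are the package's chosen
trade-off between statistical resolution and runtime; all of them scale
up through ordinary arguments.

# Known limitations

* The forward model is linear (optional soft saturation aside); real
  few-spike responses are supralinear, so absolute calibration on real
  data can differ from the synthetic calibration shown here.
* The network's receptive field (64 frames) is shorter than the spinal
  kernel at 30 Hz; context beyond ~2 s is invisible to it.
* The MAT-v5 importer covers the deposited layout (little-endian
  numeric, cell and struct arrays, zlib-compressed elements), not the
  full MAT format family (no v7.3/HDF5, sparse, or complex data).
* Noise is i.i.d. Gaussian by construction; `nu` on real data includes
  non-Gaussian and signal components, which the resampling treats as an
  unremovable floor.

# A short tour

```{r tour, eval = FALSE}
ds <- generateCohort(cohortPreset("glut_sc", nNeurons = 8,
                                  duration = 120, seed = 1))
std <- standardizeDataset(ds, targetRate = 30, targetNoise = 7, seed = 101)

models <- trainLeaveOneOut(std, seed = 201)
cnn <- lapply(names(std), function(id) inferCnn(models[[id]],
                                                std[[id]]@trace))
names(cnn) <- names(std)
truth <- lapply(std, truthRate)
shiftOptimizedCorrelation(cnn, truth, frameRate = 30)

k <- extractKernel(recordings(ds)[[1]], commonRate = 2.5)
fitExponential(k, seed = 1)
```
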