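# spikecal

Calibration and benchmarking of spike rate inference from calcium
imaging, for labs working with paired optical/electrophysiological
("ground truth") recordings — in particular from spinal cord dorsal horn
neurons expressing slow indicators such as GCaMP6s, where calcium
kernels decay over 3–4 s and firing is episodic.

Calcium fluorescence is an indirect, noisy readout of spiking. `spikecal`
implements the full loop needed to decide, quantitatively, how well a
spike-rate inference approach works on a given kind of neuron:

* **Containers & I/O** — S4 classes for paired recordings
  (`GroundTruthRecording`, `GroundTruthDataset`), a lossless plain-text
  dataset format, and a MAT-v5 importer for the deposited
  cell-attached ground-truth layout. dF/F is computed as
  `100·(F − F0)/F0` with F0 the global 10th percentile of raw
  fluorescence.
* **Synthetic ground truth** — cohort generator with dorsal-horn-like
  statistics (log-normal rate spread, burst fraction targeting the
  ≤10 ms nearest-neighbour criterion, episodic rate modulation,
  per-neuron kernel amplitude variability, dual slow/fast acquisition
  regimes), so the whole pipeline is testable without downloads.
* **Standardization** — the standardized noise level
  ν = medianₜ|ΔF/Fₜ₊₁ − ΔF/Fₜ| / √f_r (% · Hz^−1/2), and resampling of
  recordings to target frame rates and noise levels with
  frame-rate-matched Gaussian smoothing of the true spike rate
  (σ = 0.4 s at 2.5 Hz … 0.05 s at 30 Hz).
* **Kernels** — the ΔF/F response to the average action potential by
  Tikhonov-regularized deconvolution (GCV-selected weight), with
  single-exponential decay fits A·e^(−t/τ) and bootstrap confidence
  intervals, plus the linear forward model and linearity analysis.
* **Inference** — three approaches: (1) raw ΔF/F as a proxy; (2)
  non-negative AR(1) deconvolution (pool-merging, exactly equivalent to
  dense non-negative least squares); (3) a supervised convolutional
  network (conv filters 31/19/5 on 64-sample windows, 20/30/40
  features, max pooling, 10-unit dense layer) trained on smoothed true
  rates with strict leave-one-out retraining per test neuron.
* **Evaluation** — dataset-level shift-optimized correlations (with
  smoothing optimization for the uncalibrated baselines), false
  positive/negative curves over evaluation windows, 5-s segment
  comparisons within and across neurons, high-frequency spike event
  (>45 Hz) analysis, and rate-variability summaries.

## A worked example

```r
library(spikecal)

ds <- generateCohort(cohortPreset("glut_sc", nNeurons = 4,
                                  duration = 120, seed = 1))
ds
#> GroundTruthDataset 'synthetic-glutamatergic-n4-seed1': 4 neurons (glutamatergic: 4)

k <- extractKernel(recordings(ds)[[1]], commonRate = 2.5)
fitExponential(k, seed = 1)
#> KernelFit: tau = 2.71 s (90% CI [2.51, 2.90]), peak 9.72%, mean(0-2 s) 8.06%

std <- standardizeDataset(ds, targetRate = 30, targetNoise = 7, seed = 101)
std[[1]]
#> ResampledRecording 'syn001' (segment 2): 30 Hz, noise 7 (target 7), sigma 0.05 s

truth <- lapply(std, truthRate)
nnd <- lapply(std, function(r) nndDeconvolve(r@trace))
shiftOptimizedCorrelation(nnd, truth, frameRate = 30)
#>   neuronId method correlation optimalShift optimalSigma
#> 1   syn001    nnd       0.574          0.1          0.1
#> 2   syn002    nnd       0.472          0.1          0.1
#> 3   syn003    nnd       0.489          0.1          0.1
#> 4   syn004    nnd       0.510          0.1          0.1
```

Reading the output: the first neuron's extracted calcium kernel decays
with τ ≈ 2.7 s (the generator draws per-neuron kernels around τ = 3.1 s)
and a ~10% ΔF/F peak per average spike. After resampling the fast
acquisition to the benchmark condition (30 Hz, standardized noise 7),
non-negative deconvolution reaches per-neuron correlations of ~0.47–0.57
with the smoothed true spike rate, after a dataset-level +0.1 s shift
and 0.1 s evaluation smoothing. `trainLeaveOneOut()` + `inferCnn()`
produce the supervised predictions for the same comparison, and
`runBenchmark()` wraps the whole chain (cohort → kernels → training →
evaluation → tidy CSV/JSON report).

A command-line wrapper for the common steps is installed with the
package (`system.file("scripts", "spikecal", package = "spikecal")`)
with subcommands `simulate`, `convert`, `standardize`, `stats`,
`kernels`, and `run`.

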