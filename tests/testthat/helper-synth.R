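# Shared fixtures, all generated in code.

# Exponential-decay kernel sampled on a frame grid (no rise; exact for
# inverse-problem tests).
sampledExpKernel <- function(tau, amplitude, frameRate, tMax = 10) {
    tt <- seq(0, tMax, by = 1 / frameRate)
    amplitude * exp(-tt / tau)
}

# A recording whose dF/F is exactly the convolution of frame-binned spike
# counts with a sampled exponential kernel (plus optional i.i.d. noise of
# nominal standardized level nu) -- the exactly invertible forward model.
onGridRecording <- function(tau = 3.1, amplitude = 16, rate = 2,
                            dur = 300, frameRate = 2.5, nu = 0,
                            seed = 1, id = "g1") {
    set.seed(seed)
    st <- SpikeTrain(sort(runif(rpois(1, rate * dur), 0, dur)),
                     duration = dur)
    n <- round(dur * frameRate)
    counts <- tabulate(pmin(floor(spikeTimes(st) * frameRate) + 1L, n),
                       nbins = n)
    k <- sampledExpKernel(tau, amplitude, frameRate)
    sig <- as.numeric(convolve(counts, rev(k), type = "open"))[1:n]
    if (nu > 0) {
        sig <- sig + rnorm(n, 0, nu * sqrt(frameRate) /
                                  (sqrt(2) * qnorm(0.75)))
    }
    GroundTruthRecording(id, "synthetic",
                         RecordingSegment(
                             FluorescenceTrace(sig, frameRate), st))
}

# Small standardized cohort at 3 Hz (32-sample network) for cheap
# inference tests; built once per test run.
.tinyEnv <- new.env(parent = emptyenv())

tinyStandardized <- function() {
    if (is.null(.tinyEnv$std)) {
        ds <- generateCohort(cohortPreset("gaba_sc", nNeurons = 4,
                                          duration = 90, seed = 42))
        .tinyEnv$std <- standardizeDataset(ds, 3, 6, seed = 7,
                                           allowNoisier = TRUE)
    }
    .tinyEnv$std
}

tinyModel <- function() {
    if (is.null(.tinyEnv$model)) {
        std <- tinyStandardized()
        ts <- makeTrainingSet(std, exclude = "syn001")
        .tinyEnv$model <- trainModel(ts, seed = 5, epochs = 8,
                                     excludedNeuron = "syn001")
    }
    .tinyEnv$model
}
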