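test_that("noise level matches the Gaussian closed form and 1/sqrt(fr)", {
    # median|N(0, 2 sigma^2)| = sigma * sqrt(2) * qnorm(0.75)
    set.seed(21)
    x <- rnorm(200000)
    nu1 <- noiseLevel(FluorescenceTrace(x, frameRate = 1))
    expect_equal(nu1, sqrt(2) * qnorm(0.75), tolerance = 0.01)
    nu4 <- noiseLevel(FluorescenceTrace(x, frameRate = 4))
    expect_equal(nu4, nu1 / 2, tolerance = 1e-12)

    expect_equal(noiseLevel(FluorescenceTrace(rep(3, 10), 5)), 0)
    expect_error(noiseLevel(FluorescenceTrace(c(0, 1), 5)), "3 samples")

    # scaling law: per-sample SD growing as sqrt(fr) keeps nu invariant
    nus <- vapply(c(2.5, 10, 40), function(fr) {
        set.seed(22)
        noiseLevel(FluorescenceTrace(rnorm(100000, 0, sqrt(fr)), fr))
    }, numeric(1))
    expect_lt(diff(range(nus)) / mean(nus), 0.02)
})

test_that("smoothing width follows the tabulated frame-rate mapping", {
    expect_identical(sigmaForRate(2.5), 0.4)
    expect_identical(sigmaForRate(5), 0.2)
    expect_identical(sigmaForRate(10), 0.1)
    expect_identical(sigmaForRate(30), 0.05)
    expect_identical(sigmaForRate(3), 0.4)    # next-lower entry
    expect_identical(sigmaForRate(12), 0.1)
    expect_identical(sigmaForRate(40), 0.05)  # above the table
    expect_identical(sigmaForRate(1), 0.4)    # below the table
})

test_that("spikes smooth into a unit-area rate trace", {
    st <- SpikeTrain(30, duration = 60)
    r <- smoothSpikesToRate(st, 100, sigma = 0.4)
    expect_equal(max(r), 1 / (0.4 * sqrt(2 * pi)), tolerance = 1e-3)
    expect_equal(sum(r) / 100, 1, tolerance = 1e-6)

    expect_identical(unique(smoothSpikesToRate(
        SpikeTrain(numeric(0), duration = 10), 10, sigma = 0.1)), 0)

    # linearity: coincident spikes double the trace
    st2 <- SpikeTrain(c(30, 30), duration = 60)
    expect_equal(smoothSpikesToRate(st2, 100, sigma = 0.4), 2 * r)

    # integral equals spike count for interior spikes
    st3 <- simulateSpikeTrain(spikeGenConfig(2, duration = 100), seed = 23)
    keep <- spikeTimes(st3) > 3 & spikeTimes(st3) < 97
    st3 <- SpikeTrain(spikeTimes(st3)[keep], duration = 100)
    r3 <- smoothSpikesToRate(st3, 30, sigma = 0.4)
    expect_equal(sum(r3) / 30, nSpikes(st3), tolerance = 0.01)
})

test_that("resampling standardizes rate and noise with eligibility rules", {
    ds <- generateCohort(cohortPreset("glut_sc", nNeurons = 2,
                                      duration = 90, seed = 24))
    rec <- recordings(ds)[[1]]

    # fast low-noise segment resampled to the benchmark condition
    rr <- resampleRecording(rec, 30, 7, seed = 1)
    expect_equal(rr@achievedNoise, 7, tolerance = 0.02)
    expect_identical(frameRate(rr), 30)
    expect_identical(length(truthRate(rr)), length(dff(rr)))
    expect_identical(rr@sigmaSmooth, 0.05)
    # truth integrates to the spike count
    expect_equal(sum(truthRate(rr)) / 30, nSpikes(rr@spikes),
                 tolerance = 0.02)

    # identity resampling: matching target leaves the trace unchanged
    seg <- segments(rec)[[2]]
    nu0 <- noiseLevel(seg@trace)
    rrId <- resampleRecording(rec, 30, nu0, seed = 2)
    expect_identical(dff(rrId), dff(seg))
    expect_identical(rrId@achievedNoise, nu0)

    # noise cannot be removed; upsampling is refused
    expect_error(resampleRecording(rec, 30, 0.2), "no eligible segment")
    expect_error(resampleRecording(rec, 60, 7), "no eligible segment")
    expect_error(resampleRecording(rec, 30, 0.2), "noise")

    # decimation to 2.5 Hz from the fast segment averages frames
    rr25 <- resampleRecording(rec, 2.5, 20, seed = 3, segment = 2)
    expect_identical(frameRate(rr25), 2.5)
    expect_identical(rr25@sigmaSmooth, 0.4)
})

test_that("standardizeDataset is deterministic and can skip ineligible", {
    ds <- generateCohort(cohortPreset("gaba_sc", nNeurons = 3,
                                      duration = 70, seed = 25))
    s1 <- standardizeDataset(ds, 30, 7, seed = 5)
    s2 <- standardizeDataset(ds, 30, 7, seed = 5)
    expect_identical(lapply(s1, dff), lapply(s2, dff))
    expect_named(s1, neuronIds(ds))
    # an impossible condition skips (with message) rather than failing
    expect_message(
        out <- standardizeDataset(ds, 30, 0.01, seed = 5,
                                  skipIneligible = TRUE),
        "skipping")
    expect_length(out, 0L)
})
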