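test_that("simulated spike trains hit the requested mean rate", {
    # Poisson counting error: rate within 3 * sqrt(R / T)
    cfg <- spikeGenConfig(3.7, burstFraction = 0, duration = 600)
    st <- simulateSpikeTrain(cfg, seed = 1)
    emp <- nSpikes(st) / duration(st)
    expect_lt(abs(emp - 3.7), 3 * sqrt(3.7 / 600))

    # exponential ISIs have CoV ~ 1 when bursts and refractoriness are off
    cfg2 <- spikeGenConfig(3, burstFraction = 0, refractory = 0,
                           duration = 2000)
    st2 <- simulateSpikeTrain(cfg2, seed = 2)
    expect_equal(patternStats(st2)$isiCov, 1,
                 tolerance = 3 / sqrt(nSpikes(st2)) * 3)

    # regular mode is the zero-CoV test hook
    st3 <- simulateSpikeTrain(spikeGenConfig(2, duration = 100,
                                             mode = "regular"))
    expect_equal(patternStats(st3)$isiCov, 0)

    expect_error(spikeGenConfig(-1), "positive")
    expect_error(spikeGenConfig(3, burstFraction = 1.2), "0, 1")
})

test_that("burst configuration controls the 10 ms neighbour fraction", {
    # fraction of spikes in bursts maps onto the <= 10 ms nearest-neighbour
    # statistic because within-burst ISIs are 5 ms
    for (target in c(0.065, 0.16)) {
        cfg <- spikeGenConfig(3, burstFraction = target, duration = 1500)
        st <- simulateSpikeTrain(cfg, seed = round(1000 * target))
        bf <- patternStats(st)$burstFraction10ms
        # tonic near-coincidences add a few percent on top of the target
        expect_gt(bf, 100 * target * 0.7)
        expect_lt(bf, 100 * target + 8)
    }
})

test_that("fluorescence simulation is the linear forward model plus noise", {
    fm <- forwardModelConfig(3.1, 16, riseTime = 0.1)

    # empty spike train at zero target noise: flat zero trace
    fl0 <- simulateFluorescence(SpikeTrain(numeric(0), duration = 70),
                                fm, 10, targetNoise = 0)
    expect_identical(unique(dff(fl0)), 0)

    # a single spike reproduces the sampled transient; the peak equals the
    # amplitude times the shape at the first frame offset past the rise
    st1 <- SpikeTrain(10, duration = 70)
    fl1 <- simulateFluorescence(st1, fm, 10, targetNoise = 0)
    tt <- frameTimes(fl1) - 10
    expected <- 16 * spikecal:::.kernelShape(tt, 3.1, 0.1)
    # transients are truncated once below 1e-6 of the peak
    main <- expected >= 16 * 1e-5
    expect_equal(dff(fl1)[main], expected[main], tolerance = 1e-12)
    expect_lt(max(abs(dff(fl1) - expected)[!main]), 16 * 1e-5)
    expect_equal(max(dff(fl1)), 16 * max(spikecal:::.kernelShape(
        tt[tt >= 0], 3.1, 0.1)))

    # conservation: integral = amplitude * (tau + rise/2) * nSpikes up to
    # discretization and edge truncation
    st <- simulateSpikeTrain(spikeGenConfig(2, duration = 400), seed = 5)
    fl <- simulateFluorescence(st, fm, 20, targetNoise = 0)
    expect_equal(sum(dff(fl)) / 20,
                 16 * (3.1 + 0.05) * nSpikes(st),
                 tolerance = 0.03)

    # noise calibration: achieved standardized level within 2%
    for (cond in list(c(40, 1.0), c(2.54, 5.0))) {
        stq <- simulateSpikeTrain(spikeGenConfig(0.8, duration = 300),
                                  seed = 6)
        flq <- simulateFluorescence(stq, fm, cond[1], targetNoise = cond[2],
                                    seed = 7)
        expect_equal(noiseLevel(flq), cond[2], tolerance = 0.02)
    }

    # unreachable targets are refused
    busy <- simulateSpikeTrain(spikeGenConfig(5, duration = 120), seed = 8)
    expect_error(simulateFluorescence(busy, fm, 2.5, targetNoise = 0.5),
                 "unreachable")
})

test_that("saturation ceiling caps large transients", {
    st <- SpikeTrain(c(10, 10.005, 10.01, 10.015, 10.02), duration = 60)
    fm <- forwardModelConfig(3.1, 16)
    fmSat <- forwardModelConfig(3.1, 16, saturationCeiling = 30)
    lin <- max(dff(simulateFluorescence(st, fm, 10)))
    sat <- max(dff(simulateFluorescence(st, fmSat, 10)))
    expect_gt(lin, 60)
    expect_lt(sat, 30)
})

test_that("cohorts are deterministic and match their presets", {
    cfg <- cohortPreset("glut_sc", nNeurons = 21, duration = 65, seed = 9)
    ds1 <- generateCohort(cfg)
    ds2 <- generateCohort(cfg)
    f1 <- tempfile(); f2 <- tempfile()
    saveDataset(ds1, f1); saveDataset(ds2, f2)
    expect_identical(readLines(f1), readLines(f2))  # byte-identical re-run

    # per-neuron median rate within the excitatory interquartile band
    rates <- vapply(recordings(ds1), function(r) {
        st <- segments(r)[[1]]@spikes
        nSpikes(st) / duration(st)
    }, numeric(1))
    expect_gt(median(rates), 2.8)
    expect_lt(median(rates), 6.3)

    # each neuron carries one segment per regime, sharing spikes
    rec <- recordings(ds1)[[1]]
    expect_length(segments(rec), 2L)
    s1 <- spikeTimes(segments(rec)[[1]]@spikes)
    s2 <- spikeTimes(segments(rec)[[2]]@spikes)
    expect_identical(s1, s2)  # same underlying train (equal durations)
})

test_that("inhibitory preset hits its burst-fraction target", {
    ds <- generateCohort(cohortPreset("gaba_sc", nNeurons = 12,
                                      duration = 600, seed = 10))
    bf <- vapply(recordings(ds), function(r) {
        st <- segments(r)[[1]]@spikes
        if (nSpikes(st) < 2) return(NA_real_)
        patternStats(st)$burstFraction10ms
    }, numeric(1))
    expect_equal(median(bf, na.rm = TRUE), 6.5, tolerance = 0.6)
})
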