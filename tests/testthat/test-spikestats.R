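test_that("pattern statistics match brute force on a 3-spike train", {
    st <- SpikeTrain(c(0, 0.005, 1.0), duration = 2)
    ps <- patternStats(st)
    expect_equal(ps$nnDistances, c(0.005, 0.005, 0.995))
    expect_equal(ps$burstFraction10ms, 100 * 2 / 3, tolerance = 1e-9)
    expect_equal(ps$meanRate, 1.5)
    expect_error(patternStats(SpikeTrain(1, duration = 2)), "2 spikes")
})

test_that("ISI CoV separates regular from Poisson firing", {
    reg <- simulateSpikeTrain(spikeGenConfig(1, duration = 300,
                                             mode = "regular"))
    expect_equal(patternStats(reg)$isiCov, 0)
    poi <- simulateSpikeTrain(spikeGenConfig(2, burstFraction = 0,
                                             refractory = 0,
                                             duration = 3000), seed = 41)
    expect_equal(patternStats(poi)$isiCov, 1, tolerance = 0.05)
})

test_that("burst fraction is symmetric under time reversal", {
    for (s in 1:5) {
        st <- simulateSpikeTrain(spikeGenConfig(3, burstFraction = 0.2,
                                                duration = 200), seed = s)
        rev <- SpikeTrain(sort(duration(st) - spikeTimes(st)),
                          duration = duration(st))
        expect_equal(patternStats(st)$burstFraction10ms,
                     patternStats(rev)$burstFraction10ms)
    }
})

test_that("stimulation windows can be excluded from the statistics", {
    st <- SpikeTrain(c(1, 5.1, 5.15, 5.2, 9), duration = 10,
                     stimTimes = 5)
    full <- patternStats(st)
    spont <- patternStats(st, excludeStimWindow = 2)
    expect_identical(full$nSpikes, 5L)
    expect_identical(spont$nSpikes, 2L)
    expect_equal(spont$burstFraction10ms, 0)
})

test_that("high-frequency events follow the instantaneous-rate rule", {
    # 10 spikes at 100 Hz then silence: one event
    st <- SpikeTrain(seq(0, 0.09, by = 0.01), duration = 20)
    expect_length(detectHighFreqEvents(st), 1L)
    # regular 40 Hz never crosses a 45 Hz threshold
    st40 <- SpikeTrain(seq(1, 5, by = 1 / 40), duration = 20)
    expect_length(detectHighFreqEvents(st40, threshold = 45), 0L)
    # two 50 Hz doublets 10 s apart: two events at the doublet onsets
    st2 <- SpikeTrain(c(1, 1.02, 11, 11.02), duration = 20)
    ev <- detectHighFreqEvents(st2, threshold = 45)
    expect_equal(ev, c(1, 11))
    # merging: doublets 0.5 s apart collapse at the default separation
    st3 <- SpikeTrain(c(1, 1.02, 1.5, 1.52), duration = 20)
    expect_length(detectHighFreqEvents(st3, minSeparation = 1), 1L)
})

test_that("event detection equals a brute-force ISI scan", {
    bruteForce <- function(st, threshold, minSep) {
        tt <- spikeTimes(st)
        ev <- c()
        inRun <- FALSE
        for (i in seq_along(tt)[-1]) {
            fast <- (tt[i] - tt[i - 1]) < 1 / threshold
            if (fast && !inRun) ev <- c(ev, tt[i - 1])
            inRun <- fast
        }
        out <- c()
        for (e in ev) {
            if (!length(out) || e - out[length(out)] >= minSep) {
                out <- c(out, e)
            }
        }
        out
    }
    for (s in 1:6) {
        st <- simulateSpikeTrain(spikeGenConfig(4, burstFraction = 0.3,
                                                withinBurstIsi = 0.008,
                                                duration = 150), seed = s)
        expect_equal(detectHighFreqEvents(st, 45, 1),
                     bruteForce(st, 45, 1), info = paste("seed", s))
    }
})

test_that("event-triggered counts integrate the 1 s window", {
    fr <- 20
    st <- SpikeTrain(c(seq(30, 30.2, by = 0.02), 45), duration = 60)
    truth <- smoothSpikesToRate(st, fr, sigma = 0.1)
    tr <- FluorescenceTrace(truth + 1, fr)
    ev <- detectHighFreqEvents(st)
    res <- eventTriggered(ev, truth, tr,
                          inferredRates = list(same = truth,
                                               zero = rep(0, length(truth))),
                          spikes = st, window = 5)
    # identical signal: identical triggered average and counts
    expect_equal(res$average$same, res$average$truth)
    expect_equal(res$counts$same, res$counts$truth)
    # integral of the smoothed truth over 1 s ~ spikes in the event
    expect_equal(res$counts$truth, res$counts$trueSpikes, tolerance = 0.05)
    # zero rate: zero counts
    expect_identical(unique(res$counts$zero), 0)
    # counts use the 1 s window regardless of display window
    res2 <- eventTriggered(ev, truth, tr,
                           inferredRates = list(same = truth),
                           spikes = st, window = 2)
    expect_equal(res2$counts$same, res$counts$same)
    # events at the edge are dropped with a message
    stE <- SpikeTrain(c(0.5, 0.52, 30, 30.02), duration = 60)
    truthE <- smoothSpikesToRate(stE, fr, sigma = 0.1)
    expect_message(
        resE <- eventTriggered(detectHighFreqEvents(stE), truthE,
                               FluorescenceTrace(truthE, fr), window = 5),
        "dropped")
    expect_identical(resE$nDropped, 1L)
})
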