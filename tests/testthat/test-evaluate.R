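mkInferred <- function(x, fr, method = "dff") {
    new("InferredRate", rate = x, frameRate = fr, method = method,
        appliedShift = 0, appliedSmoothSigma = NULL)
}

test_that("shift optimization finds constructed delays", {
    fr <- 10
    set.seed(61)
    truth <- smoothSpikesToRate(
        simulateSpikeTrain(spikeGenConfig(2, duration = 120), seed = 61),
        fr, sigma = 0.2)
    # identity: correlation 1 at zero shift
    e0 <- shiftOptimizedCorrelation(list(a = mkInferred(truth, fr)),
                                    list(a = truth), fr)
    expect_equal(e0$correlation, 1)
    expect_equal(e0$optimalShift, 0)
    # prediction delayed by 0.4 s: optimal shift +0.4 s, correlation ~1
    delayed <- c(rep(0, 4), truth[1:(length(truth) - 4)])
    e1 <- shiftOptimizedCorrelation(list(a = mkInferred(delayed, fr)),
                                    list(a = truth), fr)
    expect_equal(e1$optimalShift, 0.4)
    expect_gt(e1$correlation, 0.999)
    # independent noise: near-zero correlation; the bound allows for the
    # maximization over the shift-and-smoothing grid
    noise <- rnorm(length(truth))
    e2 <- shiftOptimizedCorrelation(list(a = mkInferred(noise, fr)),
                                    list(a = truth), fr)
    expect_lt(abs(e2$correlation), 0.15)
    # affine rescaling leaves the correlation unchanged
    e3 <- shiftOptimizedCorrelation(
        list(a = mkInferred(3 * truth + 2, fr)), list(a = truth), fr)
    expect_equal(e3$correlation, 1)
    # zero-variance predictions are flagged by name
    expect_warning(
        shiftOptimizedCorrelation(
            list(a = mkInferred(truth, fr),
                 b = mkInferred(rep(0, length(truth)), fr)),
            list(a = truth, b = truth), fr),
        "zero-variance.*b")
})

test_that("smoothing is grid-searched for the uncalibrated baselines", {
    fr <- 10
    set.seed(62)
    truth <- smoothSpikesToRate(
        simulateSpikeTrain(spikeGenConfig(2, duration = 120), seed = 62),
        fr, sigma = 0.5)
    spiky <- smoothSpikesToRate(
        simulateSpikeTrain(spikeGenConfig(2, duration = 120), seed = 62),
        fr, sigma = 0.05)
    e <- shiftOptimizedCorrelation(list(a = mkInferred(spiky, fr, "nnd")),
                                   list(a = truth), fr)
    expect_gt(e$optimalSigma, 0)
    eCnn <- shiftOptimizedCorrelation(
        list(a = mkInferred(spiky, fr, "cnn")), list(a = truth), fr)
    expect_true(is.na(eCnn$optimalSigma))
})

test_that("FP/FN curves behave like binned counting errors", {
    fr <- 10
    st <- SpikeTrain(seq(5, 95, by = 10), duration = 100)  # 10 spikes
    counts <- spikecal:::.binSpikes(spikeTimes(st), fr, 1000)
    exact <- mkInferred(counts * fr, fr)
    ws <- c(0.5, 1, 2, 5, 20, 100)
    # exact counts: zero errors at every window
    c0 <- fpFnCurve(exact, st, ws)
    expect_equal(c0$fpRate, rep(0, length(ws)), tolerance = 1e-9)
    expect_equal(c0$fnRate, rep(0, length(ws)), tolerance = 1e-9)
    # a one-bin shift errs at small windows and heals as windows grow
    shifted <- mkInferred(c(rep(0, 5), counts[1:995]) * fr, fr)
    c1 <- fpFnCurve(shifted, st, ws)
    expect_gt(c1$fpRate[1], 0)
    expect_gt(c1$fnRate[1], 0)
    expect_equal(c1$fpRate[length(ws)], 0, tolerance = 1e-9)
    # doubling the estimate: FP = 100% of true spikes, FN = 0, at every w
    c2 <- fpFnCurve(mkInferred(2 * counts * fr, fr), st, ws)
    expect_equal(c2$fpRate, rep(100, length(ws)), tolerance = 1e-9)
    expect_equal(c2$fnRate, rep(0, length(ws)), tolerance = 1e-9)
    expect_equal(attr(c2, "bias"), 100, tolerance = 1e-9)
    # FP + FN >= |bias| with equality at the full duration
    set.seed(63)
    noisy <- mkInferred(pmax(counts * fr + rnorm(1000, 0, 3), 0), fr)
    cn <- fpFnCurve(noisy, st, c(ws, 100))
    expect_true(all(cn$fpRate + cn$fnRate >=
                        abs(attr(cn, "bias")) - 1e-9))
    last <- nrow(cn)
    expect_equal(cn$fpRate[last] + cn$fnRate[last],
                 abs(attr(cn, "bias")), tolerance = 1e-9)
})

test_that("segment comparisons score relative rates against chance", {
    fr <- 10
    dur <- 100
    set.seed(64)
    mkNeuron <- function(rate, seed) {
        st <- simulateSpikeTrain(spikeGenConfig(rate, duration = dur),
                                 seed = seed)
        counts <- spikecal:::.binSpikes(spikeTimes(st), fr, dur * fr)
        list(st = st, exact = mkInferred(counts * fr, fr))
    }
    n1 <- mkNeuron(1, 1); n2 <- mkNeuron(10, 2)
    inf <- list(a = n1$exact, b = n2$exact)
    spk <- list(a = n1$st, b = n2$st)
    # faithful inference: 100% correct in both scopes
    wi <- segmentComparison(inf, spk, scope = "within")
    ac <- segmentComparison(inf, spk, scope = "across")
    expect_equal(unname(wi$percentCorrect), 100)
    expect_equal(unname(ac$percentCorrect), 100)
    # across scope enumerates ordered neuron pairs
    expect_length(ac$perUnit, 2L)
    # permuted segments fall to chance (~50%)
    permuteSegments <- function(x, fr, segLen, seed) {
        set.seed(seed)
        n <- length(x)
        nSeg <- floor(n / (segLen * fr))
        idx <- as.vector(vapply(sample(nSeg), function(s) {
            ((s - 1) * segLen * fr + 1):(s * segLen * fr)
        }, numeric(segLen * fr)))
        mkInferred(x[idx], fr)
    }
    infP <- list(a = permuteSegments(rateValues(n1$exact), fr, 5, 11),
                 b = permuteSegments(rateValues(n2$exact), fr, 5, 12))
    wiP <- segmentComparison(infP, spk, scope = "within")
    expect_gt(unname(wiP$percentCorrect), 30)
    expect_lt(unname(wiP$percentCorrect), 70)
})

test_that("rate summaries expose CoV compression and difference recovery", {
    true <- c(a = 1, b = 2, c = 5, d = 9)
    # identical vectors: equal CoV, difference correlation 1
    rs <- rateSummary(true, true, dffMeans = true)
    expect_equal(unname(rs$cov["true"]), unname(rs$cov["inferred"]))
    expect_equal(unname(rs$pairwiseDiffCorr["inferred"]), 1)
    # constant inference: CoV 0, difference correlation 0
    rs2 <- rateSummary(true, c(a = 3, b = 3, c = 3, d = 3))
    expect_equal(unname(rs2$cov["inferred"]), 0)
    expect_equal(unname(rs2$pairwiseDiffCorr["inferred"]), 0)
    # affine inference: difference correlation 1 (scale-free recovery)
    rs3 <- rateSummary(true, 0.3 + 0.5 * true)
    expect_equal(unname(rs3$pairwiseDiffCorr["inferred"]), 1)
    expect_error(rateSummary(c(-1, 0, 1), c(-1, 0, 1)), "undefined")
})

test_that("a one-cell benchmark grid equals the direct call chain", {
    ds <- generateCohort(cohortPreset("glut_sc", nNeurons = 3,
                                      duration = 70, seed = 65))
    bg1 <- benchmarkGrid(ds, rates = 30, noises = 7,
                         methods = c("dff", "nnd"), seed = 17)
    bg2 <- benchmarkGrid(ds, rates = 30, noises = 7,
                         methods = c("dff", "nnd"), seed = 17)
    expect_identical(bg1$metrics, bg2$metrics)  # fixed seed, fixed table
    # direct chain with the grid's derived seed reproduces the dff rows
    std <- standardizeDataset(ds, 30, 7, seed = 17 + 104729L)
    truth <- lapply(std, truthRate)
    direct <- shiftOptimizedCorrelation(
        lapply(std, function(r) dffProxy(r@trace)), truth, 30)
    expect_equal(bg1$metrics$correlation[bg1$metrics$method == "dff"],
                 direct$correlation)
    # paired tests are reported per method pair
    expect_identical(nrow(bg1$tests), 1L)
    expect_true(bg1$tests$pValue >= 0 && bg1$tests$pValue <= 1)
})
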