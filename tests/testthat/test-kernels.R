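test_that("deconvolution inverts the on-grid forward model exactly", {
    rec <- onGridRecording(tau = 3.1, amplitude = 16, rate = 2, dur = 300,
                           frameRate = 2.5, nu = 0, seed = 31)
    k <- extractKernel(rec, commonRate = 2.5, reg = 1e-8)
    trueK <- ifelse(k@t < 0, 0, 16 * exp(-pmax(k@t, 0) / 3.1))
    expect_lt(max(abs(k@k - trueK)) / max(trueK), 0.01)
    # the pre-spike sanity band is ~0
    expect_lt(max(abs(k@k[k@t < 0])), 0.01 * max(trueK))

    # forward o inverse: re-predicting reproduces the trace
    pred <- forwardPredict(rec@segments[[1]]@spikes, k, 2.5,
                           nFrames = length(dff(rec@segments[[1]])))
    expect_equal(dff(pred), dff(rec@segments[[1]]), tolerance = 0.02)
})

test_that("degenerate kernel inputs are handled explicitly", {
    # all-zero trace: all-zero kernel
    st <- SpikeTrain(sort(runif(30, 0, 100)), duration = 100)
    rec0 <- GroundTruthRecording("z", "synthetic", RecordingSegment(
        FluorescenceTrace(rep(0, 250), 2.5), st))
    k0 <- extractKernel(rec0, reg = 1e-6)
    expect_lt(max(abs(k0@k)), 1e-8)

    # too few spikes
    rec1 <- GroundTruthRecording("f", "synthetic", RecordingSegment(
        FluorescenceTrace(rnorm(250), 2.5),
        SpikeTrain(c(1, 2, 3), duration = 100)))
    expect_error(extractKernel(rec1), "too few spikes.*20")

    # a rising (non-decaying) kernel fails the fit loudly
    kUp <- new("CalciumKernel", t = seq(0, 10, by = 0.4),
               k = seq(0, 10, by = 0.4), sourceRate = 2.5,
               kCov = NULL, regWeight = 0)
    expect_error(fitExponential(kUp), "decay")
})

test_that("exponential fits recover tau and amplitude summaries", {
    tt <- seq(-2, 10, by = 0.4)
    kk <- ifelse(tt < 0, 0, 10 * exp(-pmax(tt, 0) / 3.1))
    k <- new("CalciumKernel", t = tt, k = kk, sourceRate = 2.5,
             kCov = NULL, regWeight = 0)
    f <- fitExponential(k, seed = 1)
    expect_equal(f@tau, 3.1, tolerance = 1e-6)
    expect_equal(f@amplitude, 10, tolerance = 1e-6)
    expect_equal(f@peakResponse, 10)
    expect_true(f@tauCI90[1] <= f@tau && f@tau <= f@tauCI90[2])

    # mean response over (0, 2] s of a unit rectangle is 1
    kr <- new("CalciumKernel", t = tt,
              k = as.numeric(tt > 0 & tt <= 2), sourceRate = 2.5,
              kCov = NULL, regWeight = 0)
    fr <- suppressWarnings(tryCatch(fitExponential(kr, seed = 1),
                                    error = function(e) NULL))
    expect_equal(mean(kr@k[kr@t > 0 & kr@t <= 2]), 1)
})

test_that("kernel amplitude scales linearly; tau estimate does not", {
    taus <- amps <- numeric(2)
    for (i in 1:2) {
        a <- c(8, 24)[i]
        rec <- onGridRecording(tau = 3.1, amplitude = a, rate = 2,
                               dur = 300, frameRate = 2.5, nu = 0,
                               seed = 33)
        k <- extractKernel(rec, reg = 1e-8)
        f <- fitExponential(k, seed = 1)
        taus[i] <- f@tau
        amps[i] <- f@amplitude
    }
    expect_equal(amps[2] / amps[1], 3, tolerance = 0.01)
    expect_equal(taus[1], taus[2], tolerance = 0.01)
})

test_that("forward prediction is linear in the spikes", {
    tt <- seq(-2, 10, by = 0.4)
    k <- new("CalciumKernel", t = tt,
             k = ifelse(tt < 0, 0, 12 * exp(-pmax(tt, 0) / 3)),
             sourceRate = 2.5, kCov = NULL, regWeight = 0)
    # empty spikes: zero trace
    p0 <- forwardPredict(SpikeTrain(numeric(0), duration = 40), k)
    expect_identical(unique(dff(p0)), 0)
    # a delta spike reproduces the kernel
    p1 <- forwardPredict(SpikeTrain(10, duration = 40), k)
    i0 <- floor(10 * 2.5) + 1
    expect_equal(dff(p1)[i0:(i0 + 20)], k@k[k@t >= 0][1:21])
    # doubling spikes in a bin doubles the prediction
    p2 <- forwardPredict(SpikeTrain(c(10, 10), duration = 40), k)
    expect_equal(dff(p2), 2 * dff(p1))
})

test_that("linearity scatter returns the expected correlations", {
    rec <- onGridRecording(tau = 3, amplitude = 12, rate = 2, dur = 400,
                           frameRate = 30, nu = 0, seed = 34)
    k <- extractKernel(rec, commonRate = 3, reg = 1e-8,
                       window = c(-2, 10))
    ls <- linearityScatter(rec, k, rate = 3)
    expect_gt(ls$correlation, 0.99)
    # observed := -predicted gives correlation -1 by construction
    expect_equal(cor(ls$predicted, -ls$predicted), -1)

    # additive noise attenuates the correlation toward the analytic
    # signal-to-total ratio
    set.seed(35)
    sigVar <- var(ls$predicted)
    noiseSd <- sd(ls$predicted) * 1.5
    noisy <- ls$predicted + rnorm(length(ls$predicted), 0, noiseSd)
    expected <- sqrt(sigVar / (sigVar + noiseSd^2))
    expect_equal(cor(ls$predicted, noisy), expected, tolerance = 0.1)
})
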