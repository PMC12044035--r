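## Internal helpers shared across modules.

## Runs expr with a temporarily seeded RNG (Mersenne-Twister, R's default),
## restoring the caller's RNG state afterwards. seed = NULL uses the ambient
## stream (callers embedded in an already-seeded pipeline).
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    eval.parent(substitute(expr))
}

## Discrete Gaussian smoothing of a regularly sampled signal. sigma in
## seconds; kernel truncated at 4 sigma and renormalized, edges handled by
## renormalizing over the in-range support (no zero-padding bias). NAs are
## propagated: output is NA where the input is NA, and NA inputs are
## excluded from neighbouring averages.
.gaussSmooth <- function(x, frameRate, sigma) {
    if (is.null(sigma) || sigma <= 0) return(x)
    halfw <- max(1L, ceiling(4 * sigma * frameRate))
    lags <- (-halfw):halfw
    w <- exp(-0.5 * (lags / (sigma * frameRate))^2)
    n <- length(x)
    ok <- !is.na(x)
    x0 <- ifelse(ok, x, 0)
    num <- as.numeric(stats::filter(c(rep(0, halfw), x0, rep(0, halfw)),
                                    w, sides = 2))[(halfw + 1):(halfw + n)]
    den <- as.numeric(stats::filter(c(rep(0, halfw), as.numeric(ok),
                                      rep(0, halfw)),
                                    w, sides = 2))[(halfw + 1):(halfw + n)]
    out <- num / den
    out[!ok] <- NA_real_
    out
}

## Decimate a dF/F vector from sourceRate to targetRate. Integer ratios
## average consecutive frames (mimicking longer dwell-time acquisition);
## non-integer ratios apply a centered boxcar of ~ratio frames and then
## linearly interpolate onto the target grid. Upsampling is refused.
.decimate <- function(x, sourceRate, targetRate) {
    ratio <- sourceRate / targetRate
    if (ratio < 1 - 1e-9) {
        stop("cannot resample upwards: source ", sourceRate,
             " Hz < target ", targetRate, " Hz")
    }
    if (abs(ratio - round(ratio)) < 1e-9) {
        r <- as.integer(round(ratio))
        if (r == 1L) return(x)
        nOut <- length(x) %/% r
        colMeans(matrix(x[seq_len(nOut * r)], nrow = r))
    } else {
        w <- max(1L, round(ratio))
        sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
        tSrc <- (seq_along(x) - 1) / sourceRate
        nOut <- floor(length(x) / ratio)
        tOut <- (seq_len(nOut) - 1) / targetRate
        # boxcar shortens the usable range by (w-1)/2 frames on each side;
        # extend with nearest defined value before interpolating
        first <- which(!is.na(sm))[1]
        last <- max(which(!is.na(sm)))
        sm[seq_len(first - 1)] <- sm[first]
        if (last < length(sm)) sm[(last + 1):length(sm)] <- sm[last]
        stats::approx(tSrc, sm, xout = tOut, rule = 2)$y
    }
}

## Theoretical standardized noise level of i.i.d. Gaussian samples with
## per-sample SD sigma at frame rate fr: median|N(0, 2 sigma^2)| / sqrt(fr).
.nuGaussian <- function(sigma, frameRate) {
    sigma * sqrt(2) * stats::qnorm(0.75) / sqrt(frameRate)
}

## Add i.i.d. Gaussian noise to dff so the standardized noise level reaches
## `target` within 2%. The needed SD is predicted analytically assuming the
## existing and added fluctuations combine in quadrature (exact for pure
## Gaussian noise, approximate in the presence of signal), then corrected
## once by rescaling the same noise draw. Returns list(dff, achieved, sd).
.addNoiseToTarget <- function(dffVals, frameRate, target,
                              allowNoisier = FALSE) {
    measure <- function(v) {
        stats::median(abs(diff(v))) / sqrt(frameRate)
    }
    nu0 <- measure(dffVals)
    if (is.null(target) || target <= 0) {
        return(list(dff = dffVals, achieved = nu0, sd = 0))
    }
    if (nu0 > target * 1.02) {
        if (allowNoisier) {
            return(list(dff = dffVals, achieved = nu0, sd = 0))
        }
        stop(sprintf(
            "target noise unreachable: trace already at nu = %.3g > target %.3g",
            nu0, target))
    }
    if (nu0 >= target * 0.98) {
        return(list(dff = dffVals, achieved = nu0, sd = 0))
    }
    q <- sqrt(2) * stats::qnorm(0.75) / sqrt(frameRate)
    sd1 <- sqrt(max(target^2 - nu0^2, 0)) / q
    eps <- stats::rnorm(length(dffVals))
    nu1 <- measure(dffVals + sd1 * eps)
    addSq <- nu1^2 - nu0^2
    sd2 <- if (addSq > 0) sd1 * sqrt((target^2 - nu0^2) / addSq) else sd1
    out <- dffVals + sd2 * eps
    list(dff = out, achieved = measure(out), sd = sd2)
}

## Bin spike times onto a frame grid: frame i covers [(i-1)/fr, i/fr).
.binSpikes <- function(spikeTimesVec, frameRate, nFrames) {
    idx <- floor(spikeTimesVec * frameRate) + 1L
    idx[idx > nFrames] <- nFrames
    idx[idx < 1L] <- 1L
    tabulate(idx, nbins = nFrames)
}
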