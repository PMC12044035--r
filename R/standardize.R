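#' Standardized noise level of a fluorescence trace
#'
#' The median absolute dF/F difference between adjacent frames, divided by
#' the square root of the frame rate. With dF/F in percent the units are
#' percent per sqrt(Hz), making noise comparable across frame rates.
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @return numeric(1), the standardized noise level nu.
#' @examples
#' tr <- FluorescenceTrace(rnorm(1000), frameRate = 4)
#' noiseLevel(tr)  # ~ sqrt(2) * qnorm(0.75) / 2
#' @export
noiseLevel <- function(trace) {
    stopifnot(is(trace, "FluorescenceTrace"))
    if (length(trace@dff) < 3L) {
        stop("noise level needs at least 3 samples")
    }
    stats::median(abs(diff(trace@dff))) / sqrt(trace@frameRate)
}

.SIGMA_TABLE <- data.frame(
    rate = c(2.5, 5, 10, 15, 20, 25, 30),
    sigma = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.05, 0.05)
)

#' Ground-truth smoothing width for a frame rate
#'
#' Returns the standard deviation (seconds) of the Gaussian used to smooth
#' discrete spikes into the ground-truth rate at a given frame rate. The
#' mapping is tabulated at 2.5, 5, 10, 15, 20, 25 and 30 Hz; between table
#' entries the next-lower entry applies (so e.g. 3 Hz uses 0.4 s), below
#' 2.5 Hz the 2.5 Hz value applies, above 30 Hz the 30 Hz value (0.05 s).
#'
#' @param frameRate frame rate in Hz (> 0).
#' @return numeric(1), sigma in seconds.
#' @export
sigmaForRate <- function(frameRate) {
    if (frameRate <= 0) stop("'frameRate' must be positive")
    i <- findInterval(frameRate + 1e-9, .SIGMA_TABLE$rate)
    .SIGMA_TABLE$sigma[max(1L, i)]
}

#' Smooth discrete spikes into a ground-truth rate trace
#'
#' Each spike contributes a unit-area Gaussian of SD \code{sigma}, sampled
#' on the frame grid; the result is a spike rate in Hz whose integral over
#' time recovers the spike count (up to edge truncation).
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param frameRate target frame rate in Hz.
#' @param sigma Gaussian SD in seconds (> 0); defaults to
#'   \code{\link{sigmaForRate}(frameRate)}.
#' @param nFrames optional number of frames (defaults to
#'   \code{round(duration * frameRate)}).
#' @return numeric vector of length \code{nFrames}, in Hz.
#' @export
smoothSpikesToRate <- function(spikes, frameRate,
                               sigma = sigmaForRate(frameRate),
                               nFrames = NULL) {
    stopifnot(is(spikes, "SpikeTrain"))
    if (sigma <= 0) stop("'sigma' must be positive")
    if (is.null(nFrames)) {
        nFrames <- max(2L, as.integer(round(spikes@duration * frameRate)))
    }
    tFrames <- (seq_len(nFrames) - 1) / frameRate
    rate <- numeric(nFrames)
    span <- ceiling(5 * sigma * frameRate)
    for (ts in spikes@spikeTimes) {
        c0 <- floor(ts * frameRate) + 1L
        idx <- max(1L, c0 - span):min(nFrames, c0 + span)
        rate[idx] <- rate[idx] + stats::dnorm(tFrames[idx], ts, sigma)
    }
    rate
}

#' Standardize a recording to a target frame rate and noise level
#'
#' Selects an eligible segment (source frame rate at or above the target,
#' source standardized noise at or below the target), decimates the dF/F
#' trace to the target rate (averaging consecutive frames for integer
#' ratios), adds Gaussian noise to reach the target noise level within 2%,
#' and builds the smoothed ground-truth rate with the frame-rate-matched
#' smoothing width. Spikes themselves are never resampled; noise only
#' affects dF/F. By default noise is added after decimation;
#' \code{noiseBeforeDecimation} flips that order.
#'
#' @param rec a \linkS4class{GroundTruthRecording}.
#' @param targetRate target frame rate in Hz.
#' @param targetNoise target standardized noise level (percent/sqrt(Hz)).
#' @param seed optional integer seed for the noise draw.
#' @param segment optional segment index to force; default: first eligible.
#' @param sigma override for the truth-rate smoothing SD (seconds).
#' @param noiseBeforeDecimation add the calibrated noise before decimating.
#' @param allowNoisier accept a decimated trace whose own fluctuations
#'   already exceed \code{targetNoise} (signal-dominated noise measure at
#'   slow rates for very active neurons) instead of failing eligibility;
#'   the achieved level is recorded as-is.
#' @return A \linkS4class{ResampledRecording}.
#' @export
resampleRecording <- function(rec, targetRate, targetNoise, seed = NULL,
                              segment = NULL, sigma = NULL,
                              noiseBeforeDecimation = FALSE,
                              allowNoisier = FALSE) {
    stopifnot(is(rec, "GroundTruthRecording"))
    pick <- NULL
    reasons <- character(0)
    segIdx <- if (is.null(segment)) seq_along(rec@segments) else segment
    for (i in segIdx) {
        seg <- rec@segments[[i]]
        fr <- seg@trace@frameRate
        nu <- noiseLevel(seg@trace)
        if (fr < targetRate * (1 - 1e-6)) {
            reasons <- c(reasons, sprintf(
                "segment %d: frame rate %.3g Hz < target %.3g Hz", i, fr,
                targetRate))
        } else if (!allowNoisier && nu > targetNoise * 1.02) {
            reasons <- c(reasons, sprintf(
                "segment %d: noise %.3g > target %.3g", i, nu, targetNoise))
        } else {
            pick <- i
            break
        }
    }
    if (is.null(pick)) {
        stop(sprintf("neuron '%s' has no eligible segment: %s",
                     rec@neuronId, paste(reasons, collapse = "; ")))
    }
    seg <- rec@segments[[pick]]
    .withSeed(seed, {
        vals <- seg@trace@dff
        fr <- seg@trace@frameRate
        if (noiseBeforeDecimation) {
            # pre-decimation target must account for the noise reduction of
            # frame averaging (1/sqrt(ratio)); only supported for integer
            # ratios, where the scaling is exact for white noise
            ratio <- fr / targetRate
            vals <- .addNoiseToTarget(vals, fr,
                                      targetNoise * sqrt(round(ratio)))$dff
        }
        vals <- .decimate(vals, fr, targetRate)
        res <- .addNoiseToTarget(vals, targetRate, targetNoise,
                                 allowNoisier = allowNoisier)
        nOut <- length(res$dff)
        durOut <- nOut / targetRate
        keep <- seg@spikes@spikeTimes <= durOut
        spikes <- SpikeTrain(seg@spikes@spikeTimes[keep], duration = durOut,
                             stimTimes = seg@spikes@stimTimes)
        if (is.null(sigma)) sigma <- sigmaForRate(targetRate)
        new("ResampledRecording",
            trace = FluorescenceTrace(res$dff, frameRate = targetRate),
            truthRate = smoothSpikesToRate(spikes, targetRate, sigma,
                                           nFrames = nOut),
            spikes = spikes, sigmaSmooth = sigma,
            targetNoise = targetNoise, achievedNoise = res$achieved,
            neuronId = rec@neuronId, sourceSegment = as.integer(pick))
    })
}

#' Standardize every recording of a dataset
#'
#' Applies \code{\link{resampleRecording}} to each recording; per-neuron
#' noise seeds are derived deterministically from \code{seed}. Recordings
#' with no eligible segment raise an error unless \code{skipIneligible}.
#'
#' @param dataset a \linkS4class{GroundTruthDataset}.
#' @param targetRate,targetNoise as in \code{\link{resampleRecording}}.
#' @param seed integer seed.
#' @param skipIneligible drop ineligible neurons with a message instead of
#'   failing.
#' @param ... passed to \code{\link{resampleRecording}}.
#' @return Named list of \linkS4class{ResampledRecording} (by neuron id).
#' @export
standardizeDataset <- function(dataset, targetRate, targetNoise, seed = 1L,
                               skipIneligible = FALSE, ...) {
    stopifnot(is(dataset, "GroundTruthDataset"))
    out <- list()
    for (i in seq_along(dataset@recordings)) {
        rec <- dataset@recordings[[i]]
        rr <- tryCatch(
            resampleRecording(rec, targetRate, targetNoise,
                              seed = seed + 7919L * i, ...),
            error = function(e) e
        )
        if (inherits(rr, "error")) {
            if (skipIneligible) {
                message("skipping ", rec@neuronId, ": ",
                        conditionMessage(rr))
                next
            }
            stop(rr)
        }
        out[[rec@neuronId]] <- rr
    }
    out
}
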