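#' Configuration of the linear spike-to-fluorescence forward model
#'
#' The per-spike calcium transient is a linear rise over \code{riseTime}
#' followed by a single-exponential decay with time constant \code{tau}; the
#' trace is the superposition of one transient per spike, optionally passed
#' through a soft-saturating ceiling, plus i.i.d. Gaussian noise calibrated
#' to a target standardized noise level.
#'
#' @param tau decay time constant in seconds (> 0).
#' @param amplitude peak dF/F per spike, in percent (> 0).
#' @param amplitudeCvAcrossNeurons coefficient of variation of the
#'   (log-normal) per-neuron amplitude distribution used by
#'   \code{\link{generateCohort}}.
#' @param saturationCeiling optional asymptotic dF/F ceiling (percent); the
#'   saturating transform is \code{C * tanh(x / C)} (identity slope at 0).
#'   \code{NULL} (default) disables saturation.
#' @param riseTime linear rise time in seconds; a nuisance parameter not
#'   resolvable at slow sampling rates.
#' @return A validated list of class \code{"ForwardModelConfig"}.
#' @export
forwardModelConfig <- function(tau, amplitude,
                               amplitudeCvAcrossNeurons = 0.6,
                               saturationCeiling = NULL, riseTime = 0.1) {
    if (tau <= 0) stop("'tau' must be positive")
    if (amplitude <= 0) stop("'amplitude' must be positive")
    if (!is.null(saturationCeiling) && saturationCeiling <= 0) {
        stop("'saturationCeiling' must be positive or NULL")
    }
    structure(
        list(tau = tau, amplitude = amplitude,
             amplitudeCvAcrossNeurons = amplitudeCvAcrossNeurons,
             saturationCeiling = saturationCeiling, riseTime = riseTime),
        class = "ForwardModelConfig"
    )
}

## Transient shape at time t >= 0 after a spike (peak normalized to 1).
.kernelShape <- function(t, tau, riseTime) {
    ifelse(t < 0, 0,
           ifelse(t < riseTime, t / max(riseTime, .Machine$double.eps),
                  exp(-(t - riseTime) / tau)))
}

#' Simulate a dF/F trace from a spike train
#'
#' Superimposes one forward-model transient per spike, evaluated exactly at
#' the frame times (no binning error), applies the optional saturating
#' ceiling, and adds Gaussian noise calibrated so the standardized noise
#' level matches \code{targetNoise} within 2% (one corrective iteration).
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param fm a \code{\link{forwardModelConfig}}.
#' @param frameRate imaging frame rate in Hz.
#' @param targetNoise target standardized noise level in percent per
#'   sqrt(Hz); 0 or NULL for a noiseless trace.
#' @param seed optional integer seed.
#' @param allowNoisier if TRUE, a trace whose spiking signal alone already
#'   exceeds \code{targetNoise} (a real phenomenon for active neurons at
#'   slow frame rates, where the median frame-to-frame fluctuation is
#'   signal-dominated) is returned without added noise instead of raising
#'   an error; \code{\link{generateCohort}} uses this so regime noise
#'   targets act as per-neuron floors, like the spread of measured noise
#'   levels in recorded cohorts.
#' @return A \linkS4class{FluorescenceTrace} (dF/F in percent, t0 = 0).
#' @export
simulateFluorescence <- function(spikes, fm, frameRate, targetNoise = 0,
                                 seed = NULL, allowNoisier = FALSE) {
    stopifnot(is(spikes, "SpikeTrain"), inherits(fm, "ForwardModelConfig"))
    if (frameRate <= 0) stop("'frameRate' must be positive")
    nFrames <- max(2L, as.integer(round(spikes@duration * frameRate)))
    tFrames <- (seq_len(nFrames) - 1) / frameRate
    sig <- numeric(nFrames)
    # transients truncated where they fall below 1e-6 of the peak
    span <- fm$riseTime + fm$tau * log(1e6)
    spanFrames <- ceiling(span * frameRate)
    for (ts in spikes@spikeTimes) {
        i0 <- max(1L, floor(ts * frameRate) + 1L)
        i1 <- min(nFrames, i0 + spanFrames)
        if (i0 > nFrames) next
        idx <- i0:i1
        sig[idx] <- sig[idx] +
            fm$amplitude * .kernelShape(tFrames[idx] - ts, fm$tau, fm$riseTime)
    }
    if (!is.null(fm$saturationCeiling)) {
        C <- fm$saturationCeiling
        sig <- C * tanh(sig / C)
    }
    .withSeed(seed, {
        res <- .addNoiseToTarget(sig, frameRate, targetNoise,
                                 allowNoisier = allowNoisier)
        FluorescenceTrace(res$dff, frameRate = frameRate, t0 = 0)
    })
}
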