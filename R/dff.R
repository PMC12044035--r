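#' Compute dF/F from raw fluorescence
#'
#' Converts a raw fluorescence trace (arbitrary units) to dF/F in percent,
#' with the baseline F0 taken as a global percentile of the whole trace
#' (default: the 10th percentile). Percentiles use linear interpolation
#' between order statistics (\code{stats::quantile} type 7); on short traces
#' the interpolation rule visibly changes F0, so it is fixed and documented
#' here.
#'
#' @param raw numeric vector of raw fluorescence samples (finite).
#' @param frameRate imaging frame rate in Hz.
#' @param baselinePercentile percentile (0-100, exclusive) defining F0.
#' @param t0 time of the first sample in seconds.
#' @return A \linkS4class{FluorescenceTrace} with dF/F in percent:
#'   \code{100 * (F - F0) / F0}.
#' @examples
#' tr <- computeDFF(c(rep(100, 9), 200), frameRate = 2.5)
#' dff(tr)  # 0 everywhere except the last sample (100%)
#' @export
computeDFF <- function(raw, frameRate, baselinePercentile = 10, t0 = 0) {
    raw <- as.numeric(raw)
    if (anyNA(raw) || any(!is.finite(raw))) {
        stop("raw fluorescence must be finite")
    }
    if (baselinePercentile <= 0 || baselinePercentile >= 100) {
        stop("'baselinePercentile' must be strictly between 0 and 100")
    }
    f0 <- unname(stats::quantile(raw, baselinePercentile / 100, type = 7))
    if (f0 <= 0) {
        stop(sprintf("invalid baseline: F0 = %.4g is not positive", f0))
    }
    FluorescenceTrace(100 * (raw - f0) / f0, frameRate = frameRate, t0 = t0)
}
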