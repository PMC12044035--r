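#' Spike-pattern statistics of a spike train
#'
#' Computes the mean rate, the nearest-neighbour distance of every spike
#' (minimum of the gap to the previous and to the next spike, so a spike in
#' a burst is recognized whether its partner precedes or follows it), the
#' burst fraction (percent of spikes with a neighbour within 10 ms), and
#' the coefficient of variation of inter-spike intervals. Optionally drops
#' spikes within a window after each stimulation time, for spontaneous-only
#' variants.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param excludeStimWindow seconds after each stimulation time to exclude,
#'   or NULL (default) to use all spikes.
#' @return list with \code{meanRate} (Hz), \code{burstFraction10ms}
#'   (percent), \code{isiCov}, \code{nnDistances} (seconds), \code{nSpikes}.
#' @examples
#' st <- SpikeTrain(c(0, 0.005, 1.0), duration = 2)
#' patternStats(st)$burstFraction10ms  # 66.7
#' @export
patternStats <- function(spikes, excludeStimWindow = NULL) {
    stopifnot(is(spikes, "SpikeTrain"))
    st <- spikes@spikeTimes
    if (!is.null(excludeStimWindow) && length(spikes@stimTimes)) {
        for (s in spikes@stimTimes) {
            st <- st[!(st >= s & st < s + excludeStimWindow)]
        }
    }
    if (length(st) < 2L) {
        stop("pattern statistics need at least 2 spikes")
    }
    isi <- diff(st)
    nn <- pmin(c(Inf, isi), c(isi, Inf))
    list(
        meanRate = length(st) / spikes@duration,
        burstFraction10ms = 100 * mean(nn <= 0.010),
        isiCov = stats::sd(isi) / mean(isi),
        nnDistances = nn,
        nSpikes = length(st)
    )
}

#' Detect high-frequency spike events
#'
#' An event is an episode where the instantaneous ground-truth spike rate
#' exceeds \code{threshold}. By default the instantaneous rate is the
#' reciprocal inter-spike interval assigned to each gap (45 Hz corresponds
#' to an ISI below ~22.2 ms); an event is placed at the first spike of each
#' maximal run of supra-threshold gaps. The \code{"smoothed"} strategy
#' instead thresholds a finely sampled Gaussian-smoothed rate. Events
#' closer than \code{minSeparation} are merged (first kept), so that the
#' 1 s counting windows used downstream never overlap at the default.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param threshold instantaneous rate threshold in Hz (default 45).
#' @param minSeparation merge window in seconds (default 1).
#' @param strategy \code{"isi"} (default) or \code{"smoothed"}.
#' @param smoothSigma SD (s) for the smoothed-rate strategy.
#' @return numeric vector of event times (seconds), possibly empty.
#' @export
detectHighFreqEvents <- function(spikes, threshold = 45, minSeparation = 1,
                                 strategy = c("isi", "smoothed"),
                                 smoothSigma = 0.01) {
    stopifnot(is(spikes, "SpikeTrain"))
    strategy <- match.arg(strategy)
    st <- spikes@spikeTimes
    events <- numeric(0)
    if (strategy == "isi") {
        if (length(st) >= 2L) {
            hot <- diff(st) < 1 / threshold   # gap-wise supra-threshold
            starts <- which(hot & !c(FALSE, hot[-length(hot)]))
            events <- st[starts]
        }
    } else {
        if (length(st)) {
            fr <- 100
            rate <- smoothSpikesToRate(spikes, fr, sigma = smoothSigma)
            above <- rate > threshold
            starts <- which(above & !c(FALSE, above[-length(above)]))
            events <- (starts - 1) / fr
        }
    }
    if (length(events) > 1L && minSeparation > 0) {
        merged <- events[1]
        for (e in events[-1]) {
            if (e - merged[length(merged)] >= minSeparation) {
                merged <- c(merged, e)
            }
        }
        events <- merged
    }
    events
}

#' Event-triggered averages and per-event spike counts
#'
#' Aligns the ground-truth rate, the dF/F trace and any number of inferred
#' rates on a set of event times, returning the across-event mean of each
#' signal on a lag grid, plus per-event spike counts in the 1 s window
#' centered on each event (the integral of each rate over the window; for
#' the ground truth, the raw spike count is also returned). Events whose
#' display window does not fit inside the trace are dropped with a message.
#'
#' @param events numeric event times in seconds.
#' @param truthRate numeric ground-truth rate trace (Hz).
#' @param dffTrace a \linkS4class{FluorescenceTrace} on the same grid.
#' @param inferredRates named list of \linkS4class{InferredRate} (or
#'   numeric vectors) on the same grid.
#' @param spikes optional \linkS4class{SpikeTrain} for exact true counts.
#' @param window display half-window in seconds (default 5). Counts always
#'   use the 1 s window, independent of the display window.
#' @return list with \code{lags} (s), \code{average} (named list of mean
#'   traces), \code{counts} (data.frame: event time, one count column per
#'   signal), \code{nDropped}.
#' @export
eventTriggered <- function(events, truthRate, dffTrace, inferredRates =
                               list(), spikes = NULL, window = 5) {
    stopifnot(is(dffTrace, "FluorescenceTrace"))
    fr <- dffTrace@frameRate
    n <- length(dffTrace@dff)
    stopifnot(length(truthRate) == n)
    signals <- c(list(truth = truthRate, dff = dffTrace@dff),
                 lapply(inferredRates, function(x) {
                     if (is(x, "InferredRate")) x@rate else as.numeric(x)
                 }))
    halfw <- as.integer(round(window * fr))
    halfc <- as.integer(round(0.5 * fr))
    centers <- as.integer(round(events * fr)) + 1L
    ok <- centers - halfw >= 1L & centers + halfw <= n
    nDropped <- sum(!ok)
    if (nDropped) {
        message(nDropped, " event(s) too close to the trace edge dropped")
    }
    centers <- centers[ok]
    if (!length(centers)) {
        return(list(lags = numeric(0), average = NULL,
                    counts = NULL, nDropped = nDropped))
    }
    lags <- ((-halfw):halfw) / fr
    average <- lapply(signals, function(sig) {
        mat <- vapply(centers, function(cc) sig[(cc - halfw):(cc + halfw)],
                      numeric(2L * halfw + 1L))
        rowMeans(mat, na.rm = TRUE)
    })
    counts <- data.frame(event = (centers - 1L) / fr)
    for (nm in names(signals)) {
        if (nm == "dff") next   # arbitrary units, no count
        counts[[nm]] <- vapply(centers, function(cc) {
            idx <- max(1L, cc - halfc):min(n, cc + halfc)
            sum(signals[[nm]][idx], na.rm = TRUE) / fr
        }, numeric(1))
    }
    if (!is.null(spikes)) {
        counts$trueSpikes <- vapply(counts$event, function(te) {
            sum(spikes@spikeTimes >= te - 0.5 & spikes@spikeTimes <= te + 0.5)
        }, numeric(1))
    }
    list(lags = lags, average = average, counts = counts,
         nDropped = nDropped)
}
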