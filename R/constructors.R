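#' Construct a SpikeTrain
#'
#' @param spikeTimes numeric vector of spike times in seconds (sorted if not
#'   already).
#' @param duration recording duration in seconds.
#' @param stimTimes optional stimulation time points in seconds.
#' @return A \linkS4class{SpikeTrain}.
#' @examples
#' SpikeTrain(c(0.5, 1.2, 1.21), duration = 10)
#' @export
SpikeTrain <- function(spikeTimes = numeric(0), duration,
                       stimTimes = numeric(0)) {
    new("SpikeTrain",
        spikeTimes = sort(as.numeric(spikeTimes)),
        duration = as.numeric(duration),
        stimTimes = sort(as.numeric(stimTimes)))
}

#' Construct a FluorescenceTrace
#'
#' @param dff numeric dF/F samples in percent.
#' @param frameRate imaging frame rate in Hz.
#' @param t0 time of the first sample (seconds).
#' @return A \linkS4class{FluorescenceTrace}.
#' @export
FluorescenceTrace <- function(dff, frameRate, t0 = 0) {
    new("FluorescenceTrace", dff = as.numeric(dff),
        frameRate = as.numeric(frameRate), t0 = as.numeric(t0))
}

#' Construct a RecordingSegment
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param spikes a \linkS4class{SpikeTrain} on the same clock.
#' @return A \linkS4class{RecordingSegment}.
#' @export
RecordingSegment <- function(trace, spikes) {
    new("RecordingSegment", trace = trace, spikes = spikes)
}

#' Construct a GroundTruthRecording
#' @param neuronId unique neuron identifier.
#' @param cellType one of "glutamatergic", "GABAergic", "cortex", "synthetic".
#' @param segments list of \linkS4class{RecordingSegment}.
#' @return A \linkS4class{GroundTruthRecording}.
#' @export
GroundTruthRecording <- function(neuronId, cellType, segments) {
    if (is(segments, "RecordingSegment")) segments <- list(segments)
    new("GroundTruthRecording", neuronId = as.character(neuronId),
        cellType = cellType, segments = segments)
}

#' Construct a GroundTruthDataset
#' @param name dataset name.
#' @param recordings list of \linkS4class{GroundTruthRecording}.
#' @param mixed allow heterogeneous cell types.
#' @return A \linkS4class{GroundTruthDataset}.
#' @export
GroundTruthDataset <- function(name, recordings, mixed = FALSE) {
    new("GroundTruthDataset", name = name, recordings = recordings,
        mixed = mixed)
}

## ---- accessors ------------------------------------------------------------

#' @describeIn SpikeTrain-class spike times in seconds.
#' @param x object.
#' @export
spikeTimes <- function(x) x@spikeTimes

#' @describeIn SpikeTrain-class stimulation time points in seconds.
#' @export
stimTimes <- function(x) x@stimTimes

#' Number of spikes in a SpikeTrain
#' @param x a \linkS4class{SpikeTrain}.
#' @export
nSpikes <- function(x) length(x@spikeTimes)

#' dF/F samples (percent) of a trace-bearing object
#' @param x a \linkS4class{FluorescenceTrace}, \linkS4class{ResampledRecording}
#'   or \linkS4class{RecordingSegment}.
#' @export
dff <- function(x) {
    if (is(x, "FluorescenceTrace")) return(x@dff)
    if (is(x, "ResampledRecording")) return(x@trace@dff)
    if (is(x, "RecordingSegment")) return(x@trace@dff)
    stop("no dF/F in object of class ", class(x))
}

#' Frame rate (Hz) of a trace-bearing object
#' @param x an object with a fluorescence trace.
#' @export
frameRate <- function(x) {
    if (is(x, "FluorescenceTrace")) return(x@frameRate)
    if (is(x, "ResampledRecording")) return(x@trace@frameRate)
    if (is(x, "RecordingSegment")) return(x@trace@frameRate)
    if (is(x, "InferredRate")) return(x@frameRate)
    stop("no frame rate in object of class ", class(x))
}

#' Frame time grid (seconds) of a FluorescenceTrace
#' @param x a \linkS4class{FluorescenceTrace}.
#' @export
frameTimes <- function(x) {
    x@t0 + (seq_along(x@dff) - 1) / x@frameRate
}

#' Duration in seconds
#' @param x a \linkS4class{SpikeTrain} or \linkS4class{FluorescenceTrace}.
#' @export
duration <- function(x) {
    if (is(x, "SpikeTrain")) return(x@duration)
    if (is(x, "FluorescenceTrace")) return(length(x@dff) / x@frameRate)
    stop("no duration in object of class ", class(x))
}

#' Neuron id of a recording
#' @param x a \linkS4class{GroundTruthRecording} or
#'   \linkS4class{ResampledRecording}.
#' @export
neuronId <- function(x) x@neuronId

#' Cell type label of a recording
#' @param x a \linkS4class{GroundTruthRecording}.
#' @export
cellType <- function(x) x@cellType

#' Segments of a recording
#' @param x a \linkS4class{GroundTruthRecording}.
#' @export
segments <- function(x) x@segments

#' Recordings of a dataset
#' @param x a \linkS4class{GroundTruthDataset}.
#' @export
recordings <- function(x) x@recordings

#' Neuron ids of a dataset
#' @param x a \linkS4class{GroundTruthDataset}.
#' @export
neuronIds <- function(x) {
    vapply(x@recordings, function(r) r@neuronId, character(1))
}

#' Smoothed ground-truth spike rate (Hz) of a ResampledRecording
#' @param x a \linkS4class{ResampledRecording}.
#' @export
truthRate <- function(x) x@truthRate

#' Inferred rate values
#' @param x an \linkS4class{InferredRate}.
#' @export
rateValues <- function(x) x@rate

#' Inference method tag
#' @param x an \linkS4class{InferredRate}.
#' @export
inferenceMethod <- function(x) x@method

## ---- show methods ---------------------------------------------------------

setMethod("show", "SpikeTrain", function(object) {
    cat(sprintf(
        "SpikeTrain: %d spikes over %.1f s (mean rate %.2f Hz), %d stim times\n",
        length(object@spikeTimes), object@duration,
        if (object@duration > 0) length(object@spikeTimes) / object@duration
        else NA_real_,
        length(object@stimTimes)
    ))
})

setMethod("show", "FluorescenceTrace", function(object) {
    cat(sprintf(
        "FluorescenceTrace: %d frames at %.3g Hz (%.1f s), dF/F range [%.1f, %.1f] %%\n",
        length(object@dff), object@frameRate,
        length(object@dff) / object@frameRate,
        min(object@dff), max(object@dff)
    ))
})

setMethod("show", "RecordingSegment", function(object) {
    cat("RecordingSegment\n  ")
    show(object@trace)
    cat("  ")
    show(object@spikes)
})

setMethod("show", "GroundTruthRecording", function(object) {
    cat(sprintf(
        "GroundTruthRecording '%s' (%s), %d segment(s)\n",
        object@neuronId, object@cellType, length(object@segments)
    ))
    for (s in object@segments) {
        cat(sprintf(
            "  %.3g Hz, %.0f s, %d spikes\n",
            s@trace@frameRate, length(s@trace@dff) / s@trace@frameRate,
            length(s@spikes@spikeTimes)
        ))
    }
})

setMethod("show", "GroundTruthDataset", function(object) {
    types <- table(vapply(object@recordings, cellType, character(1)))
    cat(sprintf(
        "GroundTruthDataset '%s': %d neurons (%s)\n",
        object@name, length(object@recordings),
        paste(sprintf("%s: %d", names(types), types), collapse = ", ")
    ))
})

setMethod("show", "ResampledRecording", function(object) {
    cat(sprintf(
        "ResampledRecording '%s' (segment %d): %.3g Hz, noise %.3g (target %.3g), sigma %.2g s\n",
        object@neuronId, object@sourceSegment, object@trace@frameRate,
        object@achievedNoise, object@targetNoise, object@sigmaSmooth
    ))
})

setMethod("show", "CalciumKernel", function(object) {
    cat(sprintf(
        "CalciumKernel: window [%.1f, %.1f] s at %.3g Hz, peak %.2f%% dF/F\n",
        min(object@t), max(object@t), object@sourceRate, max(object@k)
    ))
})

setMethod("show", "KernelFit", function(object) {
    cat(sprintf(
        "KernelFit: tau = %.2f s (90%% CI [%.2f, %.2f]), peak %.2f%%, mean(0-2 s) %.2f%%\n",
        object@tau, object@tauCI90[1], object@tauCI90[2],
        object@peakResponse, object@meanResponse2s
    ))
})

setMethod("show", "InferredRate", function(object) {
    cat(sprintf(
        "InferredRate (%s): %d frames at %.3g Hz, shift %.2f s%s\n",
        object@method, length(object@rate), object@frameRate,
        object@appliedShift,
        if (is.null(object@appliedSmoothSigma)) ""
        else sprintf(", eval smoothing %.2f s", object@appliedSmoothSigma)
    ))
})

setMethod("show", "TrainedModel", function(object) {
    cat(sprintf(
        "TrainedModel: %.3g Hz, noise %.3g, smoothing %.3g s, excluded = %s, seed %d\n",
        object@frameRate, object@noise, object@sigmaSmooth,
        if (is.null(object@excludedNeuron)) "none" else object@excludedNeuron,
        object@seed
    ))
})
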