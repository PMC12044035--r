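#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' SpikeTrain: electrophysiologically recorded spike times
#'
#' A sorted vector of spike times (seconds from trace start) together with
#' the recording duration and, optionally, the time points of dorsal root
#' stimulation.
#'
#' @slot spikeTimes numeric, strictly non-decreasing spike times in seconds,
#'   all within \code{[0, duration]}.
#' @slot duration numeric(1), recording duration in seconds.
#' @slot stimTimes numeric, stimulation time points in seconds (may be empty).
#'
#' @exportClass SpikeTrain
setClass("SpikeTrain",
    representation(
        spikeTimes = "numeric",
        duration = "numeric",
        stimTimes = "numeric"
    ),
    prototype(spikeTimes = numeric(0), duration = 0, stimTimes = numeric(0))
)

setValidity("SpikeTrain", function(object) {
    msg <- NULL
    st <- object@spikeTimes
    if (length(object@duration) != 1L || !is.finite(object@duration) ||
        object@duration < 0) {
        msg <- c(msg, "'duration' must be a single non-negative finite number")
    }
    if (anyNA(st) || any(!is.finite(st))) {
        msg <- c(msg, "'spikeTimes' must be finite and non-NA")
    } else {
        if (is.unsorted(st)) {
            msg <- c(msg, "'spikeTimes' must be sorted ascending")
        }
        if (length(st) && (min(st) < 0 || max(st) > object@duration)) {
            msg <- c(msg, "'spikeTimes' must lie in [0, duration]")
        }
    }
    if (anyNA(object@stimTimes) || any(!is.finite(object@stimTimes))) {
        msg <- c(msg, "'stimTimes' must be finite and non-NA")
    }
    if (is.null(msg)) TRUE else msg
})

#' FluorescenceTrace: a dF/F trace sampled at a fixed frame rate
#'
#' @slot dff numeric, dF/F in percent, one value per imaging frame.
#' @slot frameRate numeric(1), imaging frame rate in Hz.
#' @slot t0 numeric(1), time of the first sample in seconds (0 after
#'   alignment; kept for provenance).
#'
#' @exportClass FluorescenceTrace
setClass("FluorescenceTrace",
    representation(dff = "numeric", frameRate = "numeric", t0 = "numeric"),
    prototype(dff = numeric(0), frameRate = 1, t0 = 0)
)

setValidity("FluorescenceTrace", function(object) {
    msg <- NULL
    if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
        object@frameRate <= 0) {
        msg <- c(msg, "'frameRate' must be a single positive number")
    }
    if (length(object@dff) < 2L) {
        msg <- c(msg, "'dff' must have at least 2 samples")
    }
    if (anyNA(object@dff) || any(!is.finite(object@dff))) {
        msg <- c(msg, "'dff' must be finite")
    }
    if (length(object@t0) != 1L || !is.finite(object@t0)) {
        msg <- c(msg, "'t0' must be a single finite number")
    }
    if (is.null(msg)) TRUE else msg
})

#' RecordingSegment: one simultaneously acquired trace/spike pair
#'
#' A fluorescence trace and the spike train recorded on the same clock.
#' Validity requires both to span the same interval within one frame period.
#'
#' @slot trace a \linkS4class{FluorescenceTrace}.
#' @slot spikes a \linkS4class{SpikeTrain}.
#'
#' @exportClass RecordingSegment
setClass("RecordingSegment",
    representation(trace = "FluorescenceTrace", spikes = "SpikeTrain")
)

setValidity("RecordingSegment", function(object) {
    traceDur <- length(object@trace@dff) / object@trace@frameRate
    framePeriod <- 1 / object@trace@frameRate
    if (abs(traceDur - object@spikes@duration) > framePeriod + 1e-9) {
        return(sprintf(
            "trace spans %.3f s but spike train claims %.3f s (> one frame apart)",
            traceDur, object@spikes@duration
        ))
    }
    TRUE
})

.CELL_TYPES <- c("glutamatergic", "GABAergic", "cortex", "synthetic")

#' GroundTruthRecording: one neuron's paired ground truth
#'
#' All segments (e.g. a slow large-FOV and a fast zoomed-in acquisition) from
#' one neuron, plus metadata.
#'
#' @slot neuronId character(1), unique within a dataset.
#' @slot cellType one of \code{"glutamatergic"}, \code{"GABAergic"},
#'   \code{"cortex"}, \code{"synthetic"}.
#' @slot segments list of \linkS4class{RecordingSegment}.
#'
#' @exportClass GroundTruthRecording
setClass("GroundTruthRecording",
    representation(
        neuronId = "character",
        cellType = "character",
        segments = "list"
    )
)

setValidity("GroundTruthRecording", function(object) {
    msg <- NULL
    if (length(object@neuronId) != 1L || !nzchar(object@neuronId)) {
        msg <- c(msg, "'neuronId' must be a single non-empty string")
    }
    if (length(object@cellType) != 1L ||
        !(object@cellType %in% .CELL_TYPES)) {
        msg <- c(msg, paste0(
            "'cellType' must be one of: ",
            paste(.CELL_TYPES, collapse = ", ")
        ))
    }
    if (!length(object@segments)) {
        msg <- c(msg, "at least one segment is required")
    }
    if (!all(vapply(object@segments, is, logical(1), "RecordingSegment"))) {
        msg <- c(msg, "'segments' must all be RecordingSegment objects")
    }
    if (is.null(msg)) TRUE else msg
})

#' GroundTruthDataset: a named collection of ground-truth recordings
#'
#' @slot name character(1).
#' @slot recordings list of \linkS4class{GroundTruthRecording} with unique
#'   neuron ids.
#' @slot mixed logical(1); if \code{FALSE}, cell types must be homogeneous.
#'
#' @exportClass GroundTruthDataset
setClass("GroundTruthDataset",
    representation(name = "character", recordings = "list", mixed = "logical"),
    prototype(name = "dataset", recordings = list(), mixed = FALSE)
)

setValidity("GroundTruthDataset", function(object) {
    msg <- NULL
    if (!length(object@recordings)) {
        msg <- c(msg, "dataset must contain at least one recording")
    }
    ok <- vapply(object@recordings, is, logical(1), "GroundTruthRecording")
    if (!all(ok)) {
        msg <- c(msg, "'recordings' must all be GroundTruthRecording objects")
    } else {
        ids <- vapply(object@recordings, function(r) r@neuronId, character(1))
        if (anyDuplicated(ids)) {
            msg <- c(msg, "neuron ids must be unique within a dataset")
        }
        types <- unique(vapply(
            object@recordings, function(r) r@cellType, character(1)
        ))
        if (!object@mixed && length(types) > 1L) {
            msg <- c(msg, "cell types are heterogeneous but 'mixed' is FALSE")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' ResampledRecording: a recording standardized to a frame rate and noise level
#'
#' @slot trace \linkS4class{FluorescenceTrace} at the target frame rate with
#'   noise added to reach the target standardized level.
#' @slot truthRate numeric, Gaussian-smoothed ground-truth spike rate (Hz) on
#'   the same frame grid as \code{trace}.
#' @slot spikes the (never resampled) \linkS4class{SpikeTrain}.
#' @slot sigmaSmooth numeric(1), smoothing SD in seconds used for
#'   \code{truthRate}.
#' @slot targetNoise numeric(1), requested standardized noise level in
#'   percent per sqrt(Hz).
#' @slot achievedNoise numeric(1), measured standardized noise level.
#' @slot neuronId character(1) and @slot sourceSegment integer(1): provenance.
#'
#' @exportClass ResampledRecording
setClass("ResampledRecording",
    representation(
        trace = "FluorescenceTrace",
        truthRate = "numeric",
        spikes = "SpikeTrain",
        sigmaSmooth = "numeric",
        targetNoise = "numeric",
        achievedNoise = "numeric",
        neuronId = "character",
        sourceSegment = "integer"
    )
)

setValidity("ResampledRecording", function(object) {
    msg <- NULL
    if (length(object@truthRate) != length(object@trace@dff)) {
        msg <- c(msg, "'truthRate' and trace must have the same length")
    }
    if (object@sigmaSmooth <= 0) {
        msg <- c(msg, "'sigmaSmooth' must be positive")
    }
    if (object@targetNoise < 0) {
        msg <- c(msg, "'targetNoise' must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

#' CalciumKernel: the dF/F response to the average action potential
#'
#' @slot t numeric, time relative to the spike in seconds (default window
#'   \code{[-2, 10]} s); covers t = 0.
#' @slot k numeric, kernel values in percent dF/F per spike.
#' @slot sourceRate numeric(1), the common sampling rate (Hz) at which the
#'   kernel was extracted.
#' @slot kCov matrix or NULL; covariance of the kernel estimate (propagated
#'   from the regularized deconvolution), used for parametric-bootstrap
#'   confidence intervals on the decay fit.
#' @slot kBoot numeric or NULL; the re-shrunk kernel (the estimator applied
#'   to its own noise-free prediction), the centering point of the
#'   bias-correcting bootstrap for the decay fit.
#' @slot kReps matrix or NULL; parametric-bootstrap kernel replicates (one
#'   column per replicate) regenerated through the full solve including
#'   re-selection of the regularization weight.
#' @slot regWeight numeric(1), the Tikhonov weight actually used.
#'
#' @exportClass CalciumKernel
setClass("CalciumKernel",
    representation(
        t = "numeric", k = "numeric", sourceRate = "numeric",
        kCov = "ANY", kBoot = "ANY", kReps = "ANY", regWeight = "numeric"
    ),
    prototype(kCov = NULL, kBoot = NULL, kReps = NULL, regWeight = 0)
)

setValidity("CalciumKernel", function(object) {
    msg <- NULL
    if (length(object@t) != length(object@k)) {
        msg <- c(msg, "'t' and 'k' must have equal length")
    }
    if (anyNA(object@k) || any(!is.finite(object@k))) {
        msg <- c(msg, "'k' must be finite")
    }
    if (length(object@t) && (min(object@t) > 0 || max(object@t) < 0)) {
        msg <- c(msg, "kernel window must cover t = 0")
    }
    if (is.null(msg)) TRUE else msg
})

#' KernelFit: single-exponential fit of a calcium kernel decay
#'
#' @slot tau numeric(1), decay time constant in seconds.
#' @slot tauCI90 numeric(2), 90% confidence interval for tau.
#' @slot amplitude numeric(1), fitted amplitude at the kernel peak (% dF/F).
#' @slot peakResponse numeric(1), max of the kernel (% dF/F).
#' @slot meanResponse2s numeric(1), mean kernel value over (0, 2] s (% dF/F).
#'
#' @exportClass KernelFit
setClass("KernelFit",
    representation(
        tau = "numeric", tauCI90 = "numeric", amplitude = "numeric",
        peakResponse = "numeric", meanResponse2s = "numeric"
    )
)

setValidity("KernelFit", function(object) {
    msg <- NULL
    if (object@tau <= 0) msg <- c(msg, "'tau' must be positive")
    if (length(object@tauCI90) != 2L) {
        msg <- c(msg, "'tauCI90' must have length 2")
    } else if (!(object@tauCI90[1] <= object@tau &&
                 object@tau <= object@tauCI90[2])) {
        msg <- c(msg, "'tauCI90' must bracket 'tau'")
    }
    if (is.null(msg)) TRUE else msg
})

#' InferredRate: a continuous spike-rate estimate for one trace
#'
#' Rates are in Hz for the supervised network and in arbitrary units for the
#' non-negative deconvolution and raw-dF/F baselines. Edge frames for which
#' the network has no full input window are NA and excluded from metrics.
#'
#' @slot rate numeric, one value per frame (NA allowed at edges).
#' @slot frameRate numeric(1), Hz.
#' @slot method one of \code{"cnn"}, \code{"nnd"}, \code{"dff"}.
#' @slot appliedShift numeric(1), temporal shift (s) applied during
#'   evaluation (0 until evaluated).
#' @slot appliedSmoothSigma numeric or NULL, evaluation smoothing SD (s).
#'
#' @exportClass InferredRate
setClass("InferredRate",
    representation(
        rate = "numeric", frameRate = "numeric", method = "character",
        appliedShift = "numeric", appliedSmoothSigma = "numericOrNULL"
    ),
    prototype(appliedShift = 0, appliedSmoothSigma = NULL)
)

setValidity("InferredRate", function(object) {
    msg <- NULL
    if (!(object@method %in% c("cnn", "nnd", "dff"))) {
        msg <- c(msg, "'method' must be one of cnn, nnd, dff")
    }
    r <- object@rate[!is.na(object@rate)]
    if (object@method != "dff" && length(r) && min(r) < 0) {
        msg <- c(msg, "rates must be non-negative (dF/F proxy exempted)")
    }
    if (is.null(msg)) TRUE else msg
})

#' TrainedModel: a trained spike-inference network with its provenance
#'
#' @slot weights list of numeric arrays (opaque; layout documented in the
#'   training code).
#' @slot config list, the network architecture (window length, filter sizes,
#'   feature counts, pooling) as produced by \code{\link{cnnConfig}}.
#' @slot frameRate numeric(1), training frame rate (Hz).
#' @slot noise numeric(1), training standardized noise level.
#' @slot sigmaSmooth numeric(1), smoothing SD (s) of the training targets.
#' @slot excludedNeuron character or NULL, the left-out neuron id.
#' @slot seed integer(1), training RNG seed.
#' @slot trainInfo list, optimizer settings and final loss.
#'
#' @exportClass TrainedModel
setClass("TrainedModel",
    representation(
        weights = "list", config = "list", frameRate = "numeric",
        noise = "numeric", sigmaSmooth = "numeric",
        excludedNeuron = "characterOrNULL", seed = "integer",
        trainInfo = "list"
    ),
    prototype(excludedNeuron = NULL, trainInfo = list())
)
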