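#' Network architecture for a given frame rate
#'
#' The regression network takes a window of dF/F samples symmetric around
#' the frame being inferred and outputs the smoothed spike rate at that
#' frame. Three convolutional layers with large filters (31, 19, 5 samples
#' on a 64-sample window; 17, 9, 3 on a 32-sample window for frame rates
#' below 15 Hz) and increasing feature counts (20, 30, 40), max pooling
#' after the second and third layer, then a 10-unit dense hidden layer.
#'
#' @param frameRate recording frame rate in Hz.
#' @return list with \code{windowLen}, \code{filterSizes},
#'   \code{features}, \code{denseUnits}.
#' @export
cnnConfig <- function(frameRate) {
    if (frameRate < 15) {
        list(windowLen = 32L, filterSizes = c(17L, 9L, 3L),
             features = c(20L, 30L, 40L), denseUnits = 10L)
    } else {
        list(windowLen = 64L, filterSizes = c(31L, 19L, 5L),
             features = c(20L, 30L, 40L), denseUnits = 10L)
    }
}

## Sliding windows of length W over x, centered: window for output frame i
## spans frames (i - W/2 + 1) .. (i + W/2) [even W], so output i exists for
## i in (W/2) .. (n - W/2). Returns list(windows = matrix, centers).
.slidingWindows <- function(x, W) {
    n <- length(x)
    if (n < W) return(list(windows = NULL, centers = integer(0)))
    nOut <- n - W + 1L
    idx <- outer(seq_len(nOut) - 1L, seq_len(W), `+`)
    halfLeft <- W %/% 2L
    list(windows = matrix(x[idx], nOut, W),
         centers = seq_len(nOut) + halfLeft - 1L)
}

#' Build a supervised training set from standardized recordings
#'
#' Extracts all full sliding windows from every standardized recording
#' (except the left-out neuron) paired with the smoothed ground-truth rate
#' at the window center. Neurons with extreme outlier mean rates can be
#' excluded so they do not dominate the regression targets.
#'
#' @param resampled named list of \linkS4class{ResampledRecording} (as from
#'   \code{\link{standardizeDataset}}); all must share frame rate, noise
#'   target and smoothing width.
#' @param exclude neuron id to leave out (the test neuron), or NULL.
#' @param excludeOutlierRates drop neurons whose mean true rate exceeds the
#'   \code{outlierQuantile} of the cohort (flag, default off).
#' @param outlierQuantile quantile for the outlier rule (default 0.95).
#' @return list with \code{windows} (matrix N x W), \code{targets} (Hz),
#'   \code{neurons} (per-window neuron id), \code{frameRate}, \code{noise},
#'   \code{sigmaSmooth}, \code{windowLen}.
#' @export
makeTrainingSet <- function(resampled, exclude = NULL,
                            excludeOutlierRates = FALSE,
                            outlierQuantile = 0.95) {
    stopifnot(length(resampled) >= 1)
    fr <- resampled[[1]]@trace@frameRate
    cfg <- cnnConfig(fr)
    keep <- names(resampled)
    if (!is.null(exclude)) keep <- setdiff(keep, exclude)
    if (excludeOutlierRates && length(keep) > 2) {
        rates <- vapply(resampled[keep], function(r) {
            length(r@spikes@spikeTimes) / r@spikes@duration
        }, numeric(1))
        keep <- keep[rates <= stats::quantile(rates, outlierQuantile)]
    }
    if (!length(keep)) {
        stop("training set is empty after exclusions")
    }
    winList <- list()
    tgtList <- list()
    nrnList <- list()
    for (id in keep) {
        rr <- resampled[[id]]
        sw <- .slidingWindows(rr@trace@dff, cfg$windowLen)
        if (is.null(sw$windows)) next
        winList[[id]] <- sw$windows
        tgtList[[id]] <- rr@truthRate[sw$centers]
        nrnList[[id]] <- rep(id, nrow(sw$windows))
    }
    if (!length(winList)) stop("no recording long enough for one window")
    list(windows = do.call(rbind, winList),
         targets = unlist(tgtList, use.names = FALSE),
         neurons = unlist(nrnList, use.names = FALSE),
         frameRate = fr,
         noise = resampled[[1]]@targetNoise,
         sigmaSmooth = resampled[[1]]@sigmaSmooth,
         windowLen = cfg$windowLen)
}

#' Train the spike-rate inference network
#'
#' Minimizes the mean-squared error between predicted and smoothed true
#' spike rates with Adam, early-stopping on a held-in validation split.
#' Inputs are z-scored with training-set statistics (stored in the model
#' and re-applied at inference). Training is deterministic for a given
#' seed. The optimizer settings are not part of the published architecture
#' and are package defaults, recorded in the returned model.
#'
#' @param trainingSet as returned by \code{\link{makeTrainingSet}}.
#' @param seed integer seed (weights init, shuffling, subsampling).
#' @param epochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param learningRate Adam step size.
#' @param maxWindows cap on the number of training windows; larger sets
#'   are subsampled uniformly (seeded) to keep CPU training tractable.
#' @param valFraction fraction held out for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param excludedNeuron id recorded as left out (provenance; defaults to
#'   the attribute left by \code{makeTrainingSet} callers).
#' @return A \linkS4class{TrainedModel}.
#' @export
trainModel <- function(trainingSet, seed = 1L, epochs = 10L,
                       batchSize = 128L, learningRate = 2.5e-3,
                       maxWindows = 2500L, valFraction = 0.1,
                       patience = 3L, excludedNeuron = NULL) {
    X <- trainingSet$windows
    y <- trainingSet$targets
    if (is.null(X) || !nrow(X)) stop("empty training set")
    cfg <- cnnConfig(trainingSet$frameRate)
    seed <- as.integer(seed)
    .withSeed(seed, {
        if (nrow(X) > maxWindows) {
            sel <- sample.int(nrow(X), maxWindows)
            X <- X[sel, , drop = FALSE]
            y <- y[sel]
        }
    })
    mu <- mean(X)
    sdv <- stats::sd(as.numeric(X))
    if (sdv <= 0) sdv <- 1
    Xs <- (X - mu) / sdv
    # a rare failure mode of small ReLU networks under aggressive steps is
    # collapse to a constant (dead) output; detect it on a training probe
    # and retrain from a different initialization
    fitSeed <- seed
    for (attempt in 1:3) {
        fit <- .cnnTrain(Xs, y,
                         cfg$filterSizes[1], cfg$filterSizes[2],
                         cfg$filterSizes[3], cfg$features[1],
                         cfg$features[2], cfg$features[3], cfg$denseUnits,
                         as.integer(epochs), as.integer(batchSize),
                         learningRate, valFraction, as.integer(patience),
                         fitSeed)
        probe <- Xs[seq_len(min(500L, nrow(Xs))), , drop = FALSE]
        pv <- .cnnPredict(fit$weights, probe,
                          cfg$filterSizes[1], cfg$filterSizes[2],
                          cfg$filterSizes[3], cfg$features[1],
                          cfg$features[2], cfg$features[3], cfg$denseUnits)
        if (stats::sd(as.numeric(pv)) > 1e-8) break
        fitSeed <- fitSeed + 1000003L
        warning("degenerate (constant-output) fit; retraining with a new ",
                "initialization")
    }
    new("TrainedModel",
        weights = fit$weights, config = cfg,
        frameRate = trainingSet$frameRate, noise = trainingSet$noise,
        sigmaSmooth = trainingSet$sigmaSmooth,
        excludedNeuron = excludedNeuron, seed = fitSeed,
        trainInfo = list(inputMean = mu, inputSd = sdv,
                         requestedSeed = seed,
                         epochs = epochs, batchSize = batchSize,
                         learningRate = learningRate,
                         maxWindows = maxWindows,
                         valLoss = fit$valLoss,
                         epochsRun = fit$epochsRun,
                         optimizer = "adam", loss = "mse"))
}

#' Infer a spike rate trace with a trained network
#'
#' Applies the network to every frame with a full input window. Edge frames
#' (half a window at each end) have no prediction and are set to NA; they
#' are excluded from all downstream metrics rather than zero-filled.
#' Negative outputs are clipped to zero.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param trace a \linkS4class{FluorescenceTrace}; its frame rate must
#'   match the model's within 10%. If the trace is visibly cleaner than
#'   the model's training noise level, a warning is issued (the model was
#'   not trained for that regime).
#' @return An \linkS4class{InferredRate} in Hz (method \code{"cnn"}).
#' @export
inferCnn <- function(model, trace) {
    stopifnot(is(model, "TrainedModel"), is(trace, "FluorescenceTrace"))
    if (abs(trace@frameRate - model@frameRate) > 0.1 * model@frameRate) {
        stop(sprintf(
            "frame rate mismatch: trace %.3g Hz vs model %.3g Hz (> 10%%)",
            trace@frameRate, model@frameRate))
    }
    nuTrace <- tryCatch(noiseLevel(trace), error = function(e) NA_real_)
    if (is.finite(nuTrace) && nuTrace < 0.5 * model@noise) {
        warning(sprintf(
            "trace noise %.3g well below the model's training level %.3g",
            nuTrace, model@noise))
    }
    cfg <- model@config
    n <- length(trace@dff)
    rate <- rep(NA_real_, n)
    sw <- .slidingWindows(trace@dff, cfg$windowLen)
    if (!is.null(sw$windows)) {
        Xs <- (sw$windows - model@trainInfo$inputMean) /
            model@trainInfo$inputSd
        pred <- .cnnPredict(model@weights, Xs,
                            cfg$filterSizes[1], cfg$filterSizes[2],
                            cfg$filterSizes[3], cfg$features[1],
                            cfg$features[2], cfg$features[3],
                            cfg$denseUnits)
        rate[sw$centers] <- pmax(as.numeric(pred), 0)
    }
    new("InferredRate", rate = rate, frameRate = trace@frameRate,
        method = "cnn", appliedShift = 0, appliedSmoothSigma = NULL)
}

#' Non-negative AR(1) deconvolution (unsupervised baseline)
#'
#' Solves \code{min ||c - dff||^2} subject to
#' \code{s_t = c_t - gamma c_{t-1} >= 0} with
#' \code{gamma = exp(-1 / (frameRate * decayTau))}, by the online
#' pool-merging algorithm, and returns the innovation train \code{s} in
#' arbitrary units. Equivalent to a dense non-negative least squares on the
#' AR(1) kernel; the pool formulation is O(n).
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param decayTau calcium decay time constant in seconds (> 0). A good
#'   default is the dataset's extracted kernel tau; 1.0 s otherwise.
#' @return An \linkS4class{InferredRate} (method \code{"nnd"}, arbitrary
#'   units).
#' @export
nndDeconvolve <- function(trace, decayTau = 1.0) {
    stopifnot(is(trace, "FluorescenceTrace"))
    if (decayTau <= 0) stop("'decayTau' must be positive")
    gamma <- exp(-1 / (trace@frameRate * decayTau))
    res <- .oasisAR1(trace@dff, gamma)
    new("InferredRate", rate = res$s, frameRate = trace@frameRate,
        method = "nnd", appliedShift = 0, appliedSmoothSigma = NULL)
}

#' Raw dF/F as a spike-rate proxy
#'
#' Identity pass-through tagged for evaluation: the evaluation layer
#' applies the same shift and smoothing optimization as for the other
#' non-calibrated baseline. Values keep their dF/F units (percent) and may
#' be negative.
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @return An \linkS4class{InferredRate} (method \code{"dff"}).
#' @export
dffProxy <- function(trace) {
    stopifnot(is(trace, "FluorescenceTrace"))
    new("InferredRate", rate = trace@dff, frameRate = trace@frameRate,
        method = "dff", appliedShift = 0, appliedSmoothSigma = NULL)
}

#' Leave-one-out model training over a standardized cohort
#'
#' Trains one model per neuron, each time excluding that neuron from the
#' training windows, so every evaluation is on unseen data. Model seeds
#' are derived from \code{seed} and the left-out position so streams do not
#' collide.
#'
#' @param resampled named list of \linkS4class{ResampledRecording}.
#' @param seed integer base seed.
#' @param ... passed to \code{\link{trainModel}}.
#' @return Named list of \linkS4class{TrainedModel}, one per neuron id.
#' @export
trainLeaveOneOut <- function(resampled, seed = 1L, ...) {
    ids <- names(resampled)
    if (length(ids) < 2) stop("leave-one-out needs at least 2 neurons")
    models <- vector("list", length(ids))
    names(models) <- ids
    for (i in seq_along(ids)) {
        ts <- makeTrainingSet(resampled, exclude = ids[i])
        models[[i]] <- trainModel(ts, seed = seed + 131L * i,
                                  excludedNeuron = ids[i], ...)
    }
    models
}
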