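## Shift a vector by k frames: positive k advances the prediction in time
## (out[i] = x[i + k]); vacated frames become NA.
.shiftVec <- function(x, k) {
    n <- length(x)
    out <- rep(NA_real_, n)
    if (k >= 0) {
        if (k < n) out[1:(n - k)] <- x[(1 + k):n]
    } else {
        if (-k < n) out[(1 - k):n] <- x[1:(n + k)]
    }
    out
}

.DEFAULT_EVAL_SIGMAS <- c(0, 0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1, 1.5, 2)

#' Dataset-level shift- (and smoothing-) optimized correlation
#'
#' For one dataset and one inference method: finds the single temporal
#' shift (grid step one frame, range \code{shiftRange}) that maximizes the
#' mean product-moment correlation between predictions and smoothed true
#' rates across all neurons, then reports per-neuron correlations at that
#' common shift. For the non-calibrated baselines (\code{dff}, \code{nnd})
#' a Gaussian evaluation smoothing SD is jointly grid-searched at the
#' dataset level; the calibrated network is evaluated unsmoothed.
#'
#' @param inferred named list of \linkS4class{InferredRate} (one per
#'   neuron).
#' @param truth named list of numeric smoothed true-rate traces (Hz) on the
#'   same frame grids.
#' @param frameRate common frame rate in Hz.
#' @param shiftRange shift search range in seconds (default \code{c(-1, 1)}).
#' @param smoothSigmas candidate evaluation smoothing SDs (seconds) for
#'   dff/nnd; \code{NULL} uses the package default grid.
#' @return data.frame with one row per neuron: \code{neuronId},
#'   \code{method}, \code{correlation}, \code{optimalShift} (s),
#'   \code{optimalSigma} (s or NA).
#' @export
shiftOptimizedCorrelation <- function(inferred, truth, frameRate,
                                      shiftRange = c(-1, 1),
                                      smoothSigmas = NULL) {
    stopifnot(length(inferred) == length(truth),
              !is.null(names(inferred)))
    method <- unique(vapply(inferred, function(x) {
        if (is(x, "InferredRate")) x@method else "dff"
    }, character(1)))
    if (length(method) > 1) stop("mixed methods in one evaluation call")
    sigmas <- if (method %in% c("dff", "nnd")) {
        if (is.null(smoothSigmas)) .DEFAULT_EVAL_SIGMAS else smoothSigmas
    } else 0
    shifts <- seq(as.integer(round(shiftRange[1] * frameRate)),
                  as.integer(round(shiftRange[2] * frameRate)))
    preds <- lapply(inferred, function(x) {
        if (is(x, "InferredRate")) x@rate else as.numeric(x)
    })
    for (id in names(preds)) {
        if (stats::sd(preds[[id]], na.rm = TRUE) == 0) {
            warning("zero-variance prediction for neuron ", id,
                    ": correlation undefined")
        }
    }
    best <- list(score = -Inf)
    for (sg in sigmas) {
        smoothed <- lapply(preds, .gaussSmooth, frameRate = frameRate,
                           sigma = sg)
        for (k in shifts) {
            cors <- mapply(function(p, tr) {
                ps <- .shiftVec(p, k)
                ok <- !is.na(ps) & !is.na(tr)
                if (sum(ok) < 3 || stats::sd(ps[ok]) == 0 ||
                    stats::sd(tr[ok]) == 0) return(NA_real_)
                stats::cor(ps[ok], tr[ok])
            }, smoothed, truth)
            score <- mean(cors, na.rm = TRUE)
            if (is.finite(score) && score > best$score) {
                best <- list(score = score, k = k, sigma = sg, cors = cors)
            }
        }
    }
    if (!is.finite(best$score)) {
        stop("no valid correlation for any shift: degenerate inputs")
    }
    data.frame(
        neuronId = names(preds),
        method = method,
        correlation = as.numeric(best$cors),
        optimalShift = best$k / frameRate,
        optimalSigma = if (method %in% c("dff", "nnd")) best$sigma
                       else NA_real_,
        row.names = NULL, stringsAsFactors = FALSE
    )
}

#' False positive / false negative curves over evaluation windows
#'
#' Bins the inferred rate (absolute Hz; calibrated methods only) and the
#' true spikes into counts per window; per window size, false positives
#' are the summed excess of estimated over true counts and false negatives
#' the summed deficit, each as a percentage of total true spikes. A
#' correctly detected but time-shifted event counts as an error at short
#' windows and is forgiven as the window grows; at the full duration the
#' signed difference is the overall rate bias.
#'
#' @param inferred an \linkS4class{InferredRate} in Hz.
#' @param spikes the ground-truth \linkS4class{SpikeTrain}.
#' @param windowSizes window sizes in seconds; default: a logarithmic grid
#'   from 0.5 s capped at the recording duration, plus the duration itself.
#' @return data.frame with \code{window}, \code{fpRate}, \code{fnRate}
#'   (percent of true spikes), with attributes \code{bias} (signed percent
#'   at full duration) and \code{relativeTo} ("true" or, when there are no
#'   true spikes, "estimated").
#' @export
fpFnCurve <- function(inferred, spikes, windowSizes = NULL) {
    stopifnot(is(inferred, "InferredRate"), is(spikes, "SpikeTrain"))
    fr <- inferred@frameRate
    rate <- inferred@rate
    ok <- which(!is.na(rate))
    if (!length(ok)) stop("all-NA inferred rate")
    core <- ok[1]:ok[length(ok)]
    rate <- rate[core]
    rate[is.na(rate)] <- 0
    t0 <- (core[1] - 1) / fr
    dur <- length(core) / fr
    st <- spikes@spikeTimes - t0
    st <- st[st >= 0 & st < dur]
    if (is.null(windowSizes)) {
        windowSizes <- 0.5 * 2^(0:ceiling(log2(600 / 0.5)))
        windowSizes <- unique(c(windowSizes[windowSizes < dur], dur))
    }
    nTrue <- length(st)
    denom <- if (nTrue > 0) nTrue else sum(rate) / fr
    relativeTo <- if (nTrue > 0) "true" else "estimated"
    if (denom <= 0) stop("no true spikes and no estimated rate: FP/FN undefined")
    res <- lapply(windowSizes, function(w) {
        nBins <- max(1L, ceiling(dur / w))
        binOfFrame <- pmin(floor(((seq_along(rate) - 0.5) / fr) / w),
                           nBins - 1L) + 1L
        est <- as.numeric(tapply(rate / fr, binOfFrame, sum))
        estFull <- numeric(nBins)
        estFull[sort(unique(binOfFrame))] <- est
        true <- tabulate(pmin(floor(st / w), nBins - 1L) + 1L,
                         nbins = nBins)
        c(fp = 100 * sum(pmax(estFull - true, 0)) / denom,
          fn = 100 * sum(pmax(true - estFull, 0)) / denom)
    })
    out <- data.frame(
        window = windowSizes,
        fpRate = vapply(res, `[[`, numeric(1), "fp"),
        fnRate = vapply(res, `[[`, numeric(1), "fn")
    )
    attr(out, "bias") <- 100 * (sum(rate) / fr - nTrue) / denom
    attr(out, "relativeTo") <- relativeTo
    out
}

## Per-segment counts for one neuron: true spike counts from raw spike
## times, estimated counts from the (possibly NA-edged) inferred rate.
## Segments without any valid inferred sample are dropped.
.segmentCounts <- function(inferred, spikes, segmentLen) {
    fr <- if (is(inferred, "InferredRate")) inferred@frameRate else
        stop("need InferredRate")
    rate <- inferred@rate
    dur <- spikes@duration
    nSeg <- floor(dur / segmentLen)
    if (nSeg < 2) return(NULL)
    true <- est <- numeric(nSeg)
    okSeg <- logical(nSeg)
    for (s in seq_len(nSeg)) {
        a <- (s - 1) * segmentLen
        b <- s * segmentLen
        true[s] <- sum(spikes@spikeTimes >= a & spikes@spikeTimes < b)
        idx <- (floor(a * fr) + 1L):min(length(rate), floor(b * fr))
        v <- rate[idx]
        okSeg[s] <- any(!is.na(v))
        est[s] <- mean(v, na.rm = TRUE) * segmentLen
    }
    list(true = true[okSeg], est = est[okSeg])
}

## Scores all pairs (ix, iy) between count vectors of two (possibly equal)
## segment sets; returns correctness per pair and the true differences.
.scorePairs <- function(trueX, estX, trueY, estY, pairs) {
    dTrue <- trueX[pairs[, 1]] - trueY[pairs[, 2]]
    dEst <- estX[pairs[, 1]] - estY[pairs[, 2]]
    keep <- dTrue != 0           # ties in truth are excluded
    dTrue <- dTrue[keep]
    dEst <- dEst[keep]
    correct <- ifelse(dEst == 0, 0.5, (sign(dEst) == sign(dTrue)) * 1)
    list(correct = correct, absDiff = abs(dTrue))
}

#' Relative spike-rate comparisons over 5-second segments
#'
#' Splits every recording into segments and asks, for pairs of segments,
#' whether the inference correctly identifies the segment with more true
#' spikes. \code{"within"} compares all segment pairs inside each neuron;
#' \code{"across"} compares segments drawn from two different neurons, for
#' every ordered neuron pair. Truth ties are excluded; inference ties get
#' half credit. Chance level is 50%. Also reported: the correlation
#' between per-pair correctness and the absolute true count difference
#' (easier pairs should be scored better).
#'
#' @param inferred named list of \linkS4class{InferredRate} per neuron.
#' @param spikes named list of \linkS4class{SpikeTrain} per neuron.
#' @param segmentLen segment length in seconds (default 5).
#' @param scope \code{"within"} or \code{"across"}.
#' @param pairsPerNeuronPair cap on sampled segment pairs per neuron pair
#'   for the across scope (default all).
#' @param seed seed for the optional pair sampling.
#' @return list with \code{scope}, \code{percentCorrect} (median across
#'   units), \code{perUnit} (per neuron, or per ordered neuron pair),
#'   \code{pairCount}, \code{correctnessVsRateDiffCorr} (mean, SD).
#' @export
segmentComparison <- function(inferred, spikes, segmentLen = 5,
                              scope = c("within", "across"),
                              pairsPerNeuronPair = Inf, seed = NULL) {
    scope <- match.arg(scope)
    stopifnot(identical(names(inferred), names(spikes)))
    ids <- names(inferred)
    counts <- lapply(ids, function(id) {
        .segmentCounts(inferred[[id]], spikes[[id]], segmentLen)
    })
    names(counts) <- ids
    counts <- Filter(Negate(is.null), counts)
    if (length(counts) < 1) stop("no neuron with >= 2 segments")
    perUnit <- c()
    corrs <- c()
    totalPairs <- 0L
    .withSeed(seed, {
        if (scope == "within") {
            for (id in names(counts)) {
                cc <- counts[[id]]
                n <- length(cc$true)
                if (n < 2) next
                pairs <- t(utils::combn(n, 2))
                sc <- .scorePairs(cc$true, cc$est, cc$true, cc$est, pairs)
                if (!length(sc$correct)) next
                perUnit[id] <- 100 * mean(sc$correct)
                totalPairs <- totalPairs + length(sc$correct)
                if (length(sc$correct) > 2 && stats::sd(sc$correct) > 0 &&
                    stats::sd(sc$absDiff) > 0) {
                    corrs <- c(corrs, stats::cor(sc$correct, sc$absDiff))
                }
            }
        } else {
            nms <- names(counts)
            for (x in nms) for (y in nms) {
                if (x == y) next
                cx <- counts[[x]]; cy <- counts[[y]]
                pairs <- as.matrix(expand.grid(seq_along(cx$true),
                                               seq_along(cy$true)))
                if (nrow(pairs) > pairsPerNeuronPair) {
                    pairs <- pairs[sample.int(nrow(pairs),
                                              pairsPerNeuronPair), ,
                                   drop = FALSE]
                }
                sc <- .scorePairs(cx$true, cx$est, cy$true, cy$est, pairs)
                if (!length(sc$correct)) next
                perUnit[paste(x, y, sep = "|")] <- 100 * mean(sc$correct)
                totalPairs <- totalPairs + length(sc$correct)
                if (length(sc$correct) > 2 && stats::sd(sc$correct) > 0 &&
                    stats::sd(sc$absDiff) > 0) {
                    corrs <- c(corrs, stats::cor(sc$correct, sc$absDiff))
                }
            }
        }
    })
    if (!length(perUnit)) stop("all comparisons degenerate (truth ties only)")
    list(scope = scope,
         percentCorrect = stats::median(perUnit),
         perUnit = perUnit,
         pairCount = totalPairs,
         correctnessVsRateDiffCorr = if (length(corrs)) {
             c(mean = mean(corrs), sd = stats::sd(corrs))
         } else c(mean = NA_real_, sd = NA_real_))
}

#' Across-neuron rate variability and pairwise-difference recovery
#'
#' Given per-neuron scalar mean rates (true and inferred, optionally mean
#' dF/F), reports the coefficient of variation of each signal across
#' neurons and the correlation between pairwise differences: for every
#' unordered neuron pair, the difference in true rates against the
#' difference in inferred rates (and against dF/F differences).
#'
#' @param trueRates named numeric vector of per-neuron true mean rates (Hz).
#' @param inferredRates matching numeric vector of inferred mean rates.
#' @param dffMeans optional matching vector of mean dF/F values.
#' @return list with \code{cov} (named: true, inferred, dff) and
#'   \code{pairwiseDiffCorr} (named: inferred, dff).
#' @export
rateSummary <- function(trueRates, inferredRates, dffMeans = NULL) {
    stopifnot(length(trueRates) == length(inferredRates),
              length(trueRates) >= 3)
    cov1 <- function(x, what) {
        if (abs(mean(x)) < .Machine$double.eps) {
            stop("CoV undefined for ", what, ": mean is zero")
        }
        stats::sd(x) / mean(x)
    }
    pr <- utils::combn(length(trueRates), 2)
    dTrue <- trueRates[pr[1, ]] - trueRates[pr[2, ]]
    dInf <- inferredRates[pr[1, ]] - inferredRates[pr[2, ]]
    diffCorr <- c(inferred = if (stats::sd(dInf) > 0)
        stats::cor(dTrue, dInf) else 0)
    covs <- c(true = cov1(trueRates, "true rates"),
              inferred = cov1(inferredRates, "inferred rates"))
    if (!is.null(dffMeans)) {
        dD <- dffMeans[pr[1, ]] - dffMeans[pr[2, ]]
        diffCorr["dff"] <- if (stats::sd(dD) > 0) stats::cor(dTrue, dD)
                           else 0
        covs["dff"] <- cov1(dffMeans, "dF/F means")
    }
    list(cov = covs, pairwiseDiffCorr = diffCorr)
}

#' Full factorial benchmark over frame rates and noise levels
#'
#' For every (frame rate, noise) cell: standardizes the dataset, runs the
#' requested inference approaches (with leave-one-out retraining per test
#' neuron for the network), and evaluates shift-optimized correlations.
#' Ineligible cells (no recording clean/fast enough) are skipped with a
#' message. Nonparametric paired comparisons (Wilcoxon signed-rank)
#' between methods are reported per cell.
#'
#' @param dataset a \linkS4class{GroundTruthDataset}.
#' @param rates frame rates (Hz) to sweep.
#' @param noises standardized noise levels to sweep.
#' @param methods subset of \code{c("dff", "nnd", "cnn")}.
#' @param seed integer seed controlling standardization noise and training.
#' @param decayTau AR(1) decay for the deconvolution baseline. The default
#'   1.0 s is the stock decay constant of the widely used source-extraction
#'   toolboxes, i.e. the baseline as practitioners run it out of the box;
#'   pass \code{"kernel"} to use the dataset's extracted kernel tau
#'   instead (an indicator-matched, stronger variant).
#' @param evalSigma override for the truth smoothing width (seconds);
#'   default: matched to each cell's frame rate.
#' @param trainArgs list of arguments passed on to \code{\link{trainModel}}.
#' @return list with \code{metrics} (tidy data.frame: one row per neuron x
#'   method x condition) and \code{tests} (per-cell paired signed-rank
#'   p-values between methods).
#' @export
benchmarkGrid <- function(dataset, rates, noises,
                          methods = c("dff", "nnd", "cnn"), seed = 1L,
                          decayTau = 1.0, evalSigma = NULL,
                          trainArgs = list()) {
    stopifnot(is(dataset, "GroundTruthDataset"))
    methods <- match.arg(methods, c("dff", "nnd", "cnn"),
                         several.ok = TRUE)
    if (identical(decayTau, "kernel")) {
        decayTau <- tryCatch({
            k <- extractKernel(dataset@recordings[[1]], commonRate = 2.5)
            fitExponential(k, seed = seed)@tau
        }, error = function(e) 1.0)
    }
    metrics <- list()
    tests <- list()
    cell <- 0L
    for (fr in rates) for (nu in noises) {
        cell <- cell + 1L
        std <- tryCatch(
            standardizeDataset(dataset, fr, nu,
                               seed = seed + 104729L * cell,
                               skipIneligible = TRUE),
            error = function(e) NULL)
        if (is.null(std) || length(std) < 2) {
            message(sprintf("cell (%.3g Hz, noise %.3g) skipped: %s",
                            fr, nu,
                            if (is.null(std)) "standardization failed"
                            else "fewer than 2 eligible neurons"))
            next
        }
        if (!is.null(evalSigma)) {
            std <- lapply(std, function(rr) {
                rr@truthRate <- smoothSpikesToRate(
                    rr@spikes, fr, evalSigma,
                    nFrames = length(rr@trace@dff))
                rr@sigmaSmooth <- evalSigma
                rr
            })
        }
        truth <- lapply(std, truthRate)
        byMethod <- list()
        if ("dff" %in% methods) {
            byMethod$dff <- lapply(std, function(rr) dffProxy(rr@trace))
        }
        if ("nnd" %in% methods) {
            byMethod$nnd <- lapply(std, function(rr) {
                nndDeconvolve(rr@trace, decayTau = decayTau)
            })
        }
        if ("cnn" %in% methods) {
            models <- do.call(trainLeaveOneOut,
                              c(list(std, seed = seed + 15485863L * cell),
                                trainArgs))
            byMethod$cnn <- lapply(names(std), function(id) {
                inferCnn(models[[id]], std[[id]]@trace)
            })
            names(byMethod$cnn) <- names(std)
        }
        cellRows <- lapply(byMethod, function(inf) {
            df <- shiftOptimizedCorrelation(inf, truth, fr)
            df$frameRate <- fr
            df$noise <- nu
            df
        })
        cellDf <- do.call(rbind, cellRows)
        metrics[[length(metrics) + 1L]] <- cellDf
        ms <- names(byMethod)
        if (length(ms) > 1) {
            comb <- utils::combn(ms, 2)
            for (j in seq_len(ncol(comb))) {
                a <- cellRows[[comb[1, j]]]$correlation
                b <- cellRows[[comb[2, j]]]$correlation
                ok <- is.finite(a) & is.finite(b)
                p <- if (sum(ok) >= 3) {
                    stats::wilcox.test(a[ok], b[ok], paired = TRUE,
                                       exact = FALSE)$p.value
                } else NA_real_
                tests[[length(tests) + 1L]] <- data.frame(
                    frameRate = fr, noise = nu,
                    methodA = comb[1, j], methodB = comb[2, j],
                    medianA = stats::median(a, na.rm = TRUE),
                    medianB = stats::median(b, na.rm = TRUE),
                    pValue = p)
            }
        }
    }
    list(metrics = if (length(metrics)) do.call(rbind, metrics) else NULL,
         tests = if (length(tests)) do.call(rbind, tests) else NULL)
}
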