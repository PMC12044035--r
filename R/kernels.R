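## Design matrix for kernel deconvolution: column j of X holds the binned
## spike counts shifted by lag (j - 1 - nPre) frames, so that X %*% k is the
## discrete convolution of the spike counts with a kernel supported on
## [-nPre, nPost] frames around the spike.
.convDesign <- function(counts, nPre, nPost) {
    n <- length(counts)
    m <- nPre + nPost + 1L
    X <- matrix(0, n, m)
    for (j in seq_len(m)) {
        lag <- j - 1L - nPre   # kernel time = lag / rate
        if (lag >= 0) {
            if (lag < n) X[(lag + 1L):n, j] <- counts[1:(n - lag)]
        } else {
            if (-lag < n) X[1:(n + lag), j] <- counts[(1 - lag):n]
        }
    }
    X
}

## Second-difference smoothness operator ((m-2) x m).
.secondDiff <- function(m) {
    if (m < 3L) return(matrix(0, 0, m))
    L <- matrix(0, m - 2L, m)
    for (i in seq_len(m - 2L)) L[i, i:(i + 2L)] <- c(1, -2, 1)
    L
}

#' Extract the calcium response kernel for the average action potential
#'
#' Solves the regularized linear deconvolution: the kernel \code{k}
#' minimizing \code{||conv(spikeCounts, k) - dff||^2 + reg * ||L k||^2}
#' with \code{L} a second-difference smoothness operator, as a dense linear
#' system on a window around the spike. All segments of the recording are
#' resampled to a common rate and stacked. Pre-spike samples are retained
#' as a sanity band (they should be ~0). The regularization weight is
#' chosen by generalized cross-validation by default and reported in the
#' result.
#'
#' @param rec a \linkS4class{GroundTruthRecording}.
#' @param commonRate common sampling rate in Hz (default 2.5).
#' @param reg \code{"gcv"} (default) or a non-negative number: the Tikhonov
#'   weight relative to \code{mean(diag(X'X))}.
#' @param window kernel window in seconds relative to the spike.
#' @param minSpikes minimum total spike count required.
#' @param excludeStim drop frames within \code{stimWindow} seconds after
#'   each stimulation time before solving.
#' @param stimWindow exclusion window in seconds.
#' @param nBootReps number of parametric-bootstrap kernel replicates to
#'   precompute for downstream confidence intervals (0 disables). Each
#'   replicate redraws the trace noise at the plug-in variance, re-selects
#'   the regularization weight on a local grid and re-solves, so the
#'   replicates carry both the estimator's noise and its selection
#'   variability.
#' @param bootSeed seed for the replicate noise draws.
#' @return A \linkS4class{CalciumKernel} carrying the estimate's covariance
#'   (for confidence intervals downstream) and the regularization weight
#'   used.
#' @export
extractKernel <- function(rec, commonRate = 2.5, reg = "gcv",
                          window = c(-2, 10), minSpikes = 20,
                          excludeStim = FALSE, stimWindow = 2,
                          nBootReps = 200, bootSeed = 1L) {
    stopifnot(is(rec, "GroundTruthRecording"))
    nPre <- as.integer(round(-window[1] * commonRate))
    nPost <- as.integer(round(window[2] * commonRate))
    m <- nPre + nPost + 1L
    totalSpikes <- sum(vapply(rec@segments,
                              function(s) length(s@spikes@spikeTimes),
                              numeric(1)))
    if (totalSpikes < minSpikes) {
        stop(sprintf("too few spikes for kernel extraction: %d < %d",
                     totalSpikes, minSpikes))
    }
    XtX <- matrix(0, m, m)
    Xty <- numeric(m)
    yty <- 0
    nTot <- 0L
    blocks <- list()
    for (seg in rec@segments) {
        if (seg@trace@frameRate < commonRate * (1 - 1e-9)) next
        y <- .decimate(seg@trace@dff, seg@trace@frameRate, commonRate)
        n <- length(y)
        counts <- .binSpikes(seg@spikes@spikeTimes, commonRate, n)
        X <- .convDesign(counts, nPre, nPost)
        if (excludeStim && length(seg@spikes@stimTimes)) {
            tFr <- (seq_len(n) - 1) / commonRate
            drop <- rep(FALSE, n)
            for (st in seg@spikes@stimTimes) {
                drop <- drop | (tFr >= st & tFr < st + stimWindow)
            }
            X <- X[!drop, , drop = FALSE]
            y <- y[!drop]
            n <- length(y)
        }
        XtX <- XtX + crossprod(X)
        Xty <- Xty + crossprod(X, y)[, 1]
        yty <- yty + sum(y^2)
        nTot <- nTot + n
        blocks[[length(blocks) + 1L]] <- list(X = X, y = y)
    }
    if (nTot == 0L) {
        stop("no segment at or above the common rate ", commonRate, " Hz")
    }
    L <- .secondDiff(m)
    LtL <- crossprod(L)
    scale <- mean(diag(XtX))
    if (scale <= 0) {
        # no spikes landed on the decimated grid or all-zero trace
        kk <- numeric(m)
        return(new("CalciumKernel",
                   t = (seq_len(m) - 1L - nPre) / commonRate, k = kk,
                   sourceRate = commonRate, kCov = NULL, regWeight = 0))
    }
    solveFor <- function(lam) {
        M <- XtX + lam * scale * LtL + 1e-10 * scale * diag(m)
        k <- solve(M, Xty)
        rss <- yty - 2 * sum(k * Xty) + sum(k * (XtX %*% k))
        df <- sum(diag(solve(M, XtX)))
        list(k = k, rss = max(rss, 0), df = df, M = M)
    }
    if (identical(reg, "gcv")) {
        lams <- 10^seq(-6, 2, length.out = 33)
        gcv <- vapply(lams, function(l) {
            s <- solveFor(l)
            nTot * s$rss / (nTot - s$df)^2
        }, numeric(1))
        lam <- lams[which.min(gcv)]
    } else {
        lam <- as.numeric(reg)
    }
    sol <- solveFor(lam)
    sigma2 <- sol$rss / max(nTot - sol$df, 1)
    Minv <- solve(sol$M)
    kCov <- sigma2 * Minv %*% XtX %*% Minv
    # the estimator applied to its own noise-free prediction: centering
    # point for the bias-correcting bootstrap of downstream fits
    kBoot <- as.numeric(Minv %*% (XtX %*% sol$k))
    kReps <- NULL
    if (nBootReps > 0) {
        # X' epsilon* has covariance sigma2 * X'X; draw via its square root
        ev <- eigen(XtX, symmetric = TRUE)
        Rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0) * sigma2), m)
        XtXk <- XtX %*% sol$k
        lamGrid <- if (identical(reg, "gcv")) {
            lam * 10^seq(-1, 1, length.out = 9)
        } else lam
        kReps <- matrix(0, m, nBootReps)
        .withSeed(bootSeed, {
            for (b in seq_len(nBootReps)) {
                xe <- Rt %*% stats::rnorm(m)     # X' epsilon*
                XtyB <- XtXk + xe
                # ||y*||^2 with E||eps*||^2 plugged in for the component
                # orthogonal to the design
                ytyB <- sum(sol$k * XtXk) + 2 * sum(sol$k * xe) +
                    nTot * sigma2
                best <- NULL
                for (l in lamGrid) {
                    Ml <- XtX + l * scale * LtL + 1e-10 * scale * diag(m)
                    kb <- solve(Ml, XtyB)
                    if (length(lamGrid) > 1) {
                        rss <- max(ytyB - 2 * sum(kb * XtyB) +
                                       sum(kb * (XtX %*% kb)), 0)
                        df <- sum(diag(solve(Ml, XtX)))
                        gcvB <- nTot * rss / (nTot - df)^2
                    } else gcvB <- 0
                    if (is.null(best) || gcvB < best$gcv) {
                        best <- list(gcv = gcvB, k = kb)
                    }
                }
                kReps[, b] <- best$k
            }
        })
    }
    new("CalciumKernel",
        t = (seq_len(m) - 1L - nPre) / commonRate, k = as.numeric(sol$k),
        sourceRate = commonRate, kCov = kCov, kBoot = kBoot,
        kReps = kReps, regWeight = lam)
}

## Fit A * exp(-(t - tPeak)/tau) to the post-peak kernel samples; returns
## c(A, tau) or NULL on failure.
.fitExpCore <- function(tt, kk) {
    pos <- kk > 0
    if (sum(pos) >= 2) {
        cf <- stats::coef(stats::lm(log(kk[pos]) ~ tt[pos]))
        tau0 <- if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else
            max(tt) / 2
        A0 <- exp(cf[1])
    } else {
        tau0 <- max(tt) / 2
        A0 <- max(kk)
    }
    tau0 <- min(max(tau0, 0.05), 50)
    fit <- tryCatch(
        minpack.lm::nlsLM(
            kk ~ A * exp(-tt / tau),
            start = list(A = max(A0, 1e-6), tau = tau0),
            lower = c(1e-9, 1e-3), upper = c(Inf, 1e3),
            control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    c(A = unname(cf["A"]), tau = unname(cf["tau"]))
}

#' Fit a single exponential to the kernel decay
#'
#' Least-squares fit of \code{A * exp(-t / tau)} to the post-peak samples
#' of a calcium kernel. The 90% confidence interval for tau is obtained by
#' a 200-resample parametric bootstrap over the deconvolution uncertainty:
#' kernel replicates are drawn from the Gaussian with the covariance
#' propagated through the regularized solve (stored on the kernel by
#' \code{\link{extractKernel}}), centered on the re-shrunk kernel so the
#' basic-bootstrap interval also corrects the shrinkage bias of the
#' regularizer, and refit. If no covariance is available, residual
#' resampling around the exponential fit is used instead.
#'
#' @param kernel a \linkS4class{CalciumKernel}.
#' @param nBoot bootstrap resamples (default 200).
#' @param level confidence level (default 0.90).
#' @param seed optional integer seed for the bootstrap.
#' @return A \linkS4class{KernelFit}.
#' @export
fitExponential <- function(kernel, nBoot = 200, level = 0.90, seed = NULL) {
    stopifnot(is(kernel, "CalciumKernel"))
    p <- which.max(kernel@k)
    post <- seq(p, length(kernel@k))
    if (length(post) < 4L) {
        stop("need at least 4 post-peak samples to fit a decay")
    }
    tt <- kernel@t[post] - kernel@t[p]
    kk <- kernel@k[post]
    est <- .fitExpCore(tt, kk)
    if (is.null(est) || est["tau"] >= 999) {
        stop("kernel does not decay: exponential fit failed")
    }
    if (!is.null(kernel@kReps)) {
        # precomputed full-pipeline replicates (noise + weight re-selection)
        taus <- apply(kernel@kReps[post, , drop = FALSE], 2, function(kb) {
            fb <- .fitExpCore(tt, kb)
            if (is.null(fb)) NA_real_ else fb["tau"]
        })
        taus <- taus[is.finite(taus)]
        ci <- if (length(taus) >= 10) {
            q <- stats::quantile(taus,
                                 c((1 - level) / 2, 1 - (1 - level) / 2),
                                 names = FALSE)
            c(max(2 * est["tau"] - q[2], 1e-3), 2 * est["tau"] - q[1])
        } else c(est["tau"], est["tau"])
        ci <- c(min(ci[1], est["tau"]), max(ci[2], est["tau"]))
        inWin <- kernel@t > 0 & kernel@t <= 2
        return(new("KernelFit",
                   tau = unname(est["tau"]), tauCI90 = unname(ci),
                   amplitude = unname(est["A"]),
                   peakResponse = max(kernel@k),
                   meanResponse2s = if (any(inWin)) {
                       mean(kernel@k[inWin])
                   } else NA_real_))
    }
    taus <- rep(NA_real_, nBoot)
    basic <- FALSE
    .withSeed(seed, {
        if (!is.null(kernel@kCov)) {
            basic <- TRUE
            center <- if (!is.null(kernel@kBoot)) kernel@kBoot[post]
                      else kk
            Csub <- kernel@kCov[post, post, drop = FALSE]
            ev <- eigen(Csub, symmetric = TRUE)
            lam <- pmax(ev$values, 0)
            Rt <- ev$vectors %*% diag(sqrt(lam), length(lam))
            for (b in seq_len(nBoot)) {
                kb <- center + as.numeric(Rt %*% stats::rnorm(length(post)))
                fb <- .fitExpCore(tt, kb)
                if (!is.null(fb)) taus[b] <- fb["tau"]
            }
        } else {
            resid <- kk - est["A"] * exp(-tt / est["tau"])
            for (b in seq_len(nBoot)) {
                kb <- est["A"] * exp(-tt / est["tau"]) +
                    sample(resid, replace = TRUE)
                fb <- .fitExpCore(tt, kb)
                if (!is.null(fb)) taus[b] <- fb["tau"]
            }
        }
    })
    taus <- taus[is.finite(taus)]
    ci <- if (length(taus) >= 10) {
        q <- stats::quantile(taus, c((1 - level) / 2, 1 - (1 - level) / 2),
                             names = FALSE)
        if (basic) {
            # basic bootstrap: reflect the replicate quantiles around the
            # point estimate, which undoes the first-order shrinkage bias
            c(max(2 * est["tau"] - q[2], 1e-3), 2 * est["tau"] - q[1])
        } else q
    } else {
        c(est["tau"], est["tau"])
    }
    ci <- c(min(ci[1], est["tau"]), max(ci[2], est["tau"]))
    inWin <- kernel@t > 0 & kernel@t <= 2
    new("KernelFit",
        tau = unname(est["tau"]), tauCI90 = unname(ci),
        amplitude = unname(est["A"]),
        peakResponse = max(kernel@k),
        meanResponse2s = if (any(inWin)) mean(kernel@k[inWin]) else NA_real_)
}

## Kernel values interpolated onto an arbitrary sampling rate.
.kernelOnGrid <- function(kernel, rate) {
    if (abs(rate - kernel@sourceRate) < 1e-9) {
        return(list(t = kernel@t, k = kernel@k))
    }
    nPre <- as.integer(round(-min(kernel@t) * rate))
    nPost <- as.integer(round(max(kernel@t) * rate))
    tt <- (seq_len(nPre + nPost + 1L) - 1L - nPre) / rate
    list(t = tt, k = stats::approx(kernel@t, kernel@k, xout = tt,
                                   rule = 2)$y)
}

#' Predict dF/F from spikes with a linear kernel
#'
#' Noise-free linear forward model: the convolution of the binned spike
#' counts with the calcium kernel on the frame grid. The kernel is linearly
#' interpolated if \code{rate} differs from its extraction rate.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param kernel a \linkS4class{CalciumKernel}.
#' @param rate frame rate of the prediction grid (Hz).
#' @param nFrames optional output length.
#' @return A \linkS4class{FluorescenceTrace} (the predicted dF/F, percent).
#' @export
forwardPredict <- function(spikes, kernel, rate = kernel@sourceRate,
                           nFrames = NULL) {
    stopifnot(is(spikes, "SpikeTrain"), is(kernel, "CalciumKernel"))
    if (is.null(nFrames)) {
        nFrames <- max(2L, as.integer(round(spikes@duration * rate)))
    }
    kg <- .kernelOnGrid(kernel, rate)
    nPre <- sum(kg$t < 0)
    counts <- .binSpikes(spikes@spikeTimes, rate, nFrames)
    X <- .convDesign(counts, nPre, length(kg$t) - nPre - 1L)
    FluorescenceTrace(as.numeric(X %*% kg$k), frameRate = rate)
}

#' Linearity of the forward model against observed dF/F
#'
#' Pairs each observed dF/F time point (resampled to \code{rate}) with the
#' linear forward-model prediction from the simultaneously recorded spikes,
#' and reports the product-moment correlation: how much of the fluorescence
#' a neuron-specific linear spike-to-calcium model explains.
#'
#' @param rec a \linkS4class{GroundTruthRecording}.
#' @param kernel the neuron's \linkS4class{CalciumKernel}.
#' @param rate comparison sampling rate in Hz (default 3).
#' @return list with \code{predicted}, \code{observed} (paired vectors over
#'   all eligible segments) and \code{correlation}.
#' @export
linearityScatter <- function(rec, kernel, rate = 3) {
    stopifnot(is(rec, "GroundTruthRecording"))
    predAll <- obsAll <- numeric(0)
    for (seg in rec@segments) {
        if (seg@trace@frameRate < rate * (1 - 1e-9)) next
        obs <- .decimate(seg@trace@dff, seg@trace@frameRate, rate)
        pred <- forwardPredict(seg@spikes, kernel, rate,
                               nFrames = length(obs))@dff
        predAll <- c(predAll, pred)
        obsAll <- c(obsAll, obs)
    }
    if (!length(predAll)) {
        stop("no segment at or above ", rate, " Hz for linearity analysis")
    }
    list(predicted = predAll, observed = obsAll,
         correlation = stats::cor(predAll, obsAll))
}
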