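#' Configuration for the synthetic spike-train generator
#'
#' The generator is a marked Poisson model: a tonic homogeneous Poisson
#' process thinned by an absolute refractory period, superimposed with
#' Poisson-seeded bursts of geometric size whose spikes are regularly spaced
#' at \code{withinBurstIsi}. \code{burstFraction} is the target fraction of
#' all spikes that belong to bursts; because \code{withinBurstIsi} is well
#' below 10 ms, it maps directly onto the fraction of spikes with a
#' nearest neighbour closer than 10 ms used to quantify burstiness.
#'
#' @param meanRate overall mean spike rate in Hz (> 0).
#' @param burstFraction fraction of spikes fired within bursts, in [0, 1].
#' @param withinBurstIsi inter-spike interval inside a burst (seconds).
#' @param burstSizeMean mean number of spikes per burst (>= 2).
#' @param refractory absolute refractory period for tonic spikes (seconds).
#' @param duration simulated duration in seconds.
#' @param mode \code{"burst-poisson"} (default) or \code{"regular"}
#'   (deterministic fixed-ISI train; a test hook with ISI CoV = 0).
#' @param rateModDepth ratio between the high- and low-activity firing
#'   rate of a slow two-state (episodic) modulation of the whole process;
#'   1 (default) disables modulation and yields a homogeneous process.
#'   Dorsal-horn-like cohorts use a depth > 1 because recorded neurons
#'   fire in episodes rather than at a constant rate.
#' @param rateModTimescale mean dwell time (seconds) of each modulation
#'   state.
#' @return A validated list of class \code{"SpikeGenConfig"}.
#' @export
spikeGenConfig <- function(meanRate, burstFraction = 0,
                           withinBurstIsi = 0.005, burstSizeMean = 3,
                           refractory = 0.003, duration = 300,
                           mode = c("burst-poisson", "regular"),
                           rateModDepth = 1, rateModTimescale = 15) {
    mode <- match.arg(mode)
    if (rateModDepth < 1) stop("'rateModDepth' must be >= 1")
    if (rateModTimescale <= 0) stop("'rateModTimescale' must be positive")
    if (meanRate <= 0) stop("'meanRate' must be positive")
    if (burstFraction < 0 || burstFraction > 1) {
        stop("'burstFraction' must be in [0, 1]")
    }
    if (burstSizeMean < 2) stop("'burstSizeMean' must be >= 2")
    if (withinBurstIsi <= 0 || withinBurstIsi >= 0.01) {
        stop("'withinBurstIsi' must be in (0, 0.01) s to count as burst firing")
    }
    if (duration <= 0) stop("'duration' must be positive")
    tonicRate <- (1 - burstFraction) * meanRate
    if (refractory > 0 && tonicRate * refractory >= 1) {
        stop("refractory period incompatible with the requested tonic rate")
    }
    structure(
        list(meanRate = meanRate, burstFraction = burstFraction,
             withinBurstIsi = withinBurstIsi, burstSizeMean = burstSizeMean,
             refractory = refractory, duration = duration, mode = mode,
             rateModDepth = rateModDepth,
             rateModTimescale = rateModTimescale),
        class = "SpikeGenConfig"
    )
}

#' Simulate a spike train
#'
#' Draws one spike train under a \code{\link{spikeGenConfig}}. The tonic
#' generation rate is inflated to compensate for refractory thinning, so the
#' empirical mean rate is unbiased. Burst onsets are Poisson with rate
#' \code{burstFraction * meanRate / burstSizeMean}; burst sizes are
#' \code{2 + Geometric} with the configured mean. If \code{rateModDepth}
#' exceeds 1, the whole process (tonic and bursts) is modulated by a slow
#' two-state telegraph factor with the configured dwell time, emulating
#' episodic firing while preserving the long-run mean rate.
#'
#' @param cfg a \code{\link{spikeGenConfig}}.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return A \linkS4class{SpikeTrain}.
#' @examples
#' st <- simulateSpikeTrain(spikeGenConfig(3.7, duration = 60), seed = 1)
#' nSpikes(st) / duration(st)
#' @export
simulateSpikeTrain <- function(cfg, seed = NULL) {
    stopifnot(inherits(cfg, "SpikeGenConfig"))
    .withSeed(seed, {
        if (cfg$mode == "regular") {
            isi <- 1 / cfg$meanRate
            times <- seq(isi / 2, cfg$duration, by = isi)
            return(SpikeTrain(times, duration = cfg$duration))
        }
        d <- cfg$rateModDepth
        # slow two-state telegraph modulation: per-time thinning factor
        # relative to the high state; equal mean dwell in both states
        # preserves the long-run mean rate
        thinAt <- function(times) rep(1, length(times))
        if (d > 1) {
            edges <- 0
            while (edges[length(edges)] < cfg$duration) {
                edges <- c(edges, edges[length(edges)] +
                               stats::rexp(1, 1 / cfg$rateModTimescale))
            }
            hiFirst <- stats::runif(1) < 0.5
            thinAt <- function(times) {
                seg <- findInterval(times, edges)
                hi <- (seg %% 2 == if (hiFirst) 1 else 0)
                ifelse(hi, 1, 1 / d)
            }
        }
        modBoost <- if (d > 1) 2 * d / (1 + d) else 1
        tonicTarget <- (1 - cfg$burstFraction) * cfg$meanRate
        genRate <- tonicTarget / (1 - tonicTarget * cfg$refractory) *
            modBoost
        nTonic <- stats::rpois(1, genRate * cfg$duration)
        tonic <- sort(stats::runif(nTonic, 0, cfg$duration))
        if (d > 1 && length(tonic)) {
            tonic <- tonic[stats::runif(length(tonic)) <= thinAt(tonic)]
        }
        if (cfg$refractory > 0 && length(tonic) > 1) {
            keep <- rep(TRUE, length(tonic))
            lastKept <- tonic[1]
            for (i in seq_along(tonic)[-1]) {
                if (tonic[i] - lastKept < cfg$refractory) {
                    keep[i] <- FALSE
                } else {
                    lastKept <- tonic[i]
                }
            }
            tonic <- tonic[keep]
        }
        burst <- numeric(0)
        if (cfg$burstFraction > 0) {
            eventRate <- cfg$burstFraction * cfg$meanRate /
                cfg$burstSizeMean * modBoost
            nEvents <- stats::rpois(1, eventRate * cfg$duration)
            onsets <- stats::runif(nEvents, 0, cfg$duration)
            if (d > 1 && length(onsets)) {
                onsets <- onsets[stats::runif(length(onsets)) <=
                                     thinAt(onsets)]
                nEvents <- length(onsets)
            }
            sizes <- 2L + stats::rgeom(nEvents, 1 / (cfg$burstSizeMean - 1))
            burst <- unlist(lapply(seq_len(nEvents), function(i) {
                onsets[i] + (seq_len(sizes[i]) - 1) * cfg$withinBurstIsi
            }), use.names = FALSE)
            burst <- burst[burst <= cfg$duration]
        }
        SpikeTrain(sort(c(tonic, burst)), duration = cfg$duration)
    })
}
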