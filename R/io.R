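## On-disk dataset dialect
##
## One JSON file per dataset. Floating-point payloads are serialized as
## strings with 17 significant digits, which round-trips IEEE-754 doubles
## exactly; everything else is plain JSON. Layout:
##   { "format": "spikecal-dataset", "version": 1, "name": ...,
##     "neurons": [ { "neuron_id", "cell_type",
##                    "segments": [ { "dff": [...], "frame_rate", "t0",
##                                    "spike_times": [...],
##                                    "stim_times": [...] } ] } ] }

.num2str <- function(x) sprintf("%.17g", as.numeric(x))
.str2num <- function(x) as.numeric(unlist(x, use.names = FALSE))

#' Save a ground-truth dataset to disk
#'
#' Writes the documented JSON dialect (doubles as 17-significant-digit
#' strings, so \code{loadDataset} restores every field bit-identically).
#'
#' @param dataset a \linkS4class{GroundTruthDataset}.
#' @param path output file path (conventionally \code{.json}).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{loadDataset}}
#' @export
saveDataset <- function(dataset, path) {
    stopifnot(is(dataset, "GroundTruthDataset"))
    validObject(dataset)
    neurons <- lapply(dataset@recordings, function(rec) {
        list(
            neuron_id = rec@neuronId,
            cell_type = rec@cellType,
            segments = lapply(rec@segments, function(seg) {
                list(
                    dff = .num2str(seg@trace@dff),
                    frame_rate = .num2str(seg@trace@frameRate),
                    t0 = .num2str(seg@trace@t0),
                    duration = .num2str(seg@spikes@duration),
                    spike_times = .num2str(seg@spikes@spikeTimes),
                    stim_times = .num2str(seg@spikes@stimTimes)
                )
            })
        )
    })
    obj <- list(
        format = "spikecal-dataset", version = 1L,
        name = dataset@name, mixed = dataset@mixed, neurons = neurons
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
    invisible(path)
}

#' Load a ground-truth dataset from disk
#'
#' Reads a file written by \code{\link{saveDataset}}. Units are restored as
#' written: dF/F in percent, times in seconds.
#'
#' @param path path to a dataset file.
#' @return A \linkS4class{GroundTruthDataset}.
#' @export
loadDataset <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (dir.exists(path)) stop("'path' is a directory, expected a dataset file: ", path)
    obj <- jsonlite::read_json(path)
    if (is.null(obj$format) || obj$format != "spikecal-dataset") {
        stop("malformed dataset file ", path, ": missing format marker")
    }
    req <- function(x, field, where) {
        if (is.null(x)) {
            stop(sprintf("malformed dataset %s: missing field '%s' in %s",
                         path, field, where))
        }
        x
    }
    recs <- lapply(obj$neurons, function(n) {
        id <- req(n$neuron_id, "neuron_id", "neuron entry")
        segs <- lapply(req(n$segments, "segments", id), function(s) {
            RecordingSegment(
                FluorescenceTrace(
                    .str2num(req(s$dff, "dff", id)),
                    frameRate = .str2num(req(s$frame_rate, "frame_rate", id)),
                    t0 = .str2num(req(s$t0, "t0", id))
                ),
                SpikeTrain(
                    .str2num(s$spike_times),
                    duration = .str2num(req(s$duration, "duration", id)),
                    stimTimes = .str2num(s$stim_times)
                )
            )
        })
        GroundTruthRecording(id, req(n$cell_type, "cell_type", id), segs)
    })
    GroundTruthDataset(obj$name, recs, mixed = isTRUE(obj$mixed))
}
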