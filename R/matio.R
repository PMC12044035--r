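## Minimal MAT-v5 reader, covering the subset used by deposited paired
## ground-truth files: little-endian numeric arrays (any integer/float
## storage type), char arrays, cell arrays, struct arrays, and
## zlib-compressed elements. Sparse matrices, objects, complex data and
## big-endian files are rejected with a clear error.

.MI_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L, `6` = 4L,
               `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L, `16` = 1L)

.readMiData <- function(con, type, nbytes) {
    n <- nbytes / .MI_SIZES[[as.character(type)]]
    switch(as.character(type),
        `1` = readBin(con, "integer", n, size = 1, signed = TRUE,
                      endian = "little"),
        `2` = readBin(con, "integer", n, size = 1, signed = FALSE,
                      endian = "little"),
        `3` = readBin(con, "integer", n, size = 2, signed = TRUE,
                      endian = "little"),
        `4` = readBin(con, "integer", n, size = 2, signed = FALSE,
                      endian = "little"),
        `5` = readBin(con, "integer", n, size = 4, endian = "little"),
        `6` = as.numeric(readBin(con, "integer", n, size = 4,
                                 endian = "little")),
        `7` = readBin(con, "double", n, size = 4, endian = "little"),
        `9` = readBin(con, "double", n, size = 8, endian = "little"),
        `16` = readBin(con, "integer", n, size = 1, signed = FALSE,
                       endian = "little"),
        stop("unsupported MAT data type: ", type)
    )
}

## Reads one tag+data subelement (handling the packed small-element form)
## and skips the padding to the next 8-byte boundary.
.readElement <- function(con) {
    word <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(word) == 0L) return(NULL)
    small <- bitwAnd(bitwShiftR(word, 16L), 0xFFFFL)
    if (small != 0L) {
        type <- bitwAnd(word, 0xFFFFL)
        data <- .readMiData(con, type, small)
        if (small < 4L) readBin(con, "raw", 4L - small)
        return(list(type = type, data = data))
    }
    type <- word
    nbytes <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (type == 15L) {  # miCOMPRESSED: recurse into the inflated payload
        payload <- readBin(con, "raw", nbytes)
        raw <- memDecompress(payload, type = "gzip")
        con2 <- rawConnection(raw)
        on.exit(close(con2))
        return(.readElement(con2))
    }
    if (type == 14L) {  # miMATRIX: parse in place
        data <- .readMatrix(con, nbytes)
        return(list(type = type, data = data$value, name = data$name))
    }
    data <- .readMiData(con, type, nbytes)
    pad <- (8L - nbytes %% 8L) %% 8L
    if (pad) readBin(con, "raw", pad)
    list(type = type, data = data)
}

.readMatrix <- function(con, nbytes) {
    flagsEl <- .readElement(con)
    flags <- flagsEl$data
    class <- bitwAnd(flags[1], 0xFFL)
    if (bitwAnd(flags[1], bitwShiftL(1L, 11L)) != 0L) {
        stop("complex MAT arrays are not supported")
    }
    dims <- .readElement(con)$data
    nameEl <- .readElement(con)
    name <- rawToChar(as.raw(nameEl$data))
    value <- switch(as.character(class),
        `1` = {  # cell array
            cells <- vector("list", prod(dims))
            for (i in seq_along(cells)) {
                cells[[i]] <- .readElement(con)$data
            }
            cells
        },
        `2` = {  # struct array
            flen <- .readElement(con)$data
            fnamesRaw <- .readElement(con)$data
            nf <- length(fnamesRaw) / flen
            fnames <- vapply(seq_len(nf), function(i) {
                bytes <- fnamesRaw[((i - 1) * flen + 1):(i * flen)]
                rawToChar(as.raw(bytes[bytes != 0]))
            }, character(1))
            nel <- prod(dims)
            out <- vector("list", nel)
            for (e in seq_len(nel)) {
                fields <- stats::setNames(vector("list", nf), fnames)
                for (f in seq_len(nf)) {
                    fields[[f]] <- .readElement(con)$data
                }
                out[[e]] <- fields
            }
            if (nel == 1L) out[[1]] else out
        },
        `4` = {  # char array
            codes <- .readElement(con)$data
            intToUtf8(codes[codes != 0])
        },
        `6` = , `7` = , `8` = , `9` = , `10` = , `11` = , `12` = , `13` = {
            x <- as.numeric(.readElement(con)$data)
            if (length(dims) == 2L && any(dims == 1L)) x
            else array(x, dim = dims)
        },
        stop("unsupported MAT array class: ", class)
    )
    list(name = name, value = value)
}

#' Read a MATLAB level-5 (.mat) file
#'
#' A minimal reader for the deposited paired ground-truth layout: numeric
#' arrays, char arrays, cell arrays and struct arrays, uncompressed or
#' zlib-compressed, little-endian. Returns a named list of the file's
#' top-level variables; struct arrays become (lists of) named lists.
#'
#' @param path path to a \code{.mat} file (MAT-file version 5).
#' @return Named list of variables.
#' @export
readMat5 <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    header <- readBin(con, "raw", 128)
    version <- readBin(header[125:126], "integer", 1, size = 2,
                       endian = "little")
    endian <- rawToChar(header[127:128])
    if (endian == "MI") stop("big-endian MAT files are not supported")
    if (endian != "IM" || version != 256L) {
        stop(path, " is not a MAT-v5 file (try v7, not v7.3/HDF5)")
    }
    vars <- list()
    repeat {
        el <- .readElement(con)
        if (is.null(el)) break
        nm <- if (!is.null(el$name) && nzchar(el$name)) el$name
              else sprintf("var%d", length(vars) + 1L)
        vars[[nm]] <- el$data
    }
    vars
}

#' Import paired ground truth from the deposited MAT layout
#'
#' Each \code{.mat} file holds one neuron as a cell array of recording
#' structs (default variable \code{CAttached}), each struct with a dF/F
#' trace, its time base and detected spike events. Spike events are stored
#' as indices on a 10 kHz clock in the deposited files, hence the default
#' \code{apScale = 1e4} converting them to seconds; dF/F is stored as a
#' fraction, hence \code{dffScale = 100} converting to percent.
#'
#' @param dir directory containing one \code{.mat} file per neuron.
#' @param cellType label to attach to the imported recordings.
#' @param var name of the per-neuron cell-array variable.
#' @param fluoField,timeField,eventField struct field names for the dF/F
#'   trace, its time base (seconds) and the spike events.
#' @param apScale divisor converting stored spike events to seconds.
#' @param dffScale multiplier converting stored dF/F to percent.
#' @return A \linkS4class{GroundTruthDataset} (one recording per file,
#'   segments in file order).
#' @export
importCascadeMat <- function(dir, cellType = "glutamatergic",
                             var = "CAttached", fluoField = "fluo_mean",
                             timeField = "fluo_time",
                             eventField = "events_AP",
                             apScale = 1e4, dffScale = 100) {
    files <- sort(list.files(dir, pattern = "\\.mat$", full.names = TRUE))
    if (!length(files)) stop("no .mat files found in ", dir)
    recs <- lapply(files, function(f) {
        vars <- readMat5(f)
        if (is.null(vars[[var]])) {
            stop("malformed ground-truth file ", f, ": no variable '", var, "'")
        }
        entries <- vars[[var]]
        if (!is.list(entries)) entries <- list(entries)
        segs <- lapply(entries, function(s) {
            for (fld in c(fluoField, timeField, eventField)) {
                if (is.null(s[[fld]])) {
                    stop("malformed ground-truth file ", f,
                         ": struct lacks field '", fld, "'")
                }
            }
            tt <- as.numeric(s[[timeField]])
            fr <- 1 / stats::median(diff(tt))
            spikes <- as.numeric(s[[eventField]]) / apScale - tt[1]
            dur <- length(tt) / fr
            spikes <- spikes[spikes >= 0 & spikes <= dur]
            RecordingSegment(
                FluorescenceTrace(as.numeric(s[[fluoField]]) * dffScale,
                                  frameRate = fr, t0 = 0),
                SpikeTrain(spikes, duration = dur)
            )
        })
        GroundTruthRecording(
            neuronId = sub("\\.mat$", "", basename(f)),
            cellType = cellType, segments = segs
        )
    })
    GroundTruthDataset(basename(normalizePath(dir)), recs)
}
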