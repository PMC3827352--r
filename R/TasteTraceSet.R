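#' Container for a set of taste-cell calcium traces
#'
#' \code{TasteTraceSet} extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: rows are time points
#' on a shared uniform grid (row metadata column \code{time_s}), columns
#' are cells, and the assays hold either the computed \code{"ratio"}
#' (F340/F380) matrix or the raw \code{"f340"}/\code{"f380"} channel
#' matrices. The stimulus epochs shared by all cells live in
#' \code{metadata(x)$epochs} as a \code{DataFrame} with columns
#' \code{stimulus}, \code{concentration_mM}, \code{start_s}, \code{end_s}.
#' Per-cell annotation (cohort label, simulation ground truth) lives in
#' \code{colData}.
#'
#' @aliases TasteTraceSet epochs epochs<- traceTimes samplingInterval
#'   groundTruth epochs,TasteTraceSet-method
#'   epochs<-,TasteTraceSet-method traceTimes,TasteTraceSet-method
#'   samplingInterval,TasteTraceSet-method groundTruth,TasteTraceSet-method
#'   computeRatio,TasteTraceSet-method
#'
#' @param ratio numeric matrix (time points x cells), or \code{NULL} when
#'   raw channels are given.
#' @param f340,f380 optional raw channel matrices with the same shape.
#' @param time numeric vector of sample times in seconds, uniformly
#'   spaced.
#' @param epochs \code{DataFrame}/\code{data.frame} of stimulus epochs
#'   (columns \code{stimulus}, \code{concentration_mM}, \code{start_s},
#'   \code{end_s}), or a list of \linkS4class{StimulusEpoch}.
#' @param colData optional \code{DataFrame} of per-cell annotation.
#'
#' @return a \code{TasteTraceSet}.
#' @examples
#' tr <- simulateTrace(TraceGenParams(amplitudePct = 40), seed = 1)
#' tr
#' epochs(tr)
#' head(traceTimes(tr))
#' @export
setClass("TasteTraceSet", contains = "SummarizedExperiment")

.epochsToDataFrame <- function(epochs) {
    if (is(epochs, "DataFrame")) return(epochs)
    if (is.data.frame(epochs)) return(S4Vectors::DataFrame(epochs))
    if (is(epochs, "StimulusEpoch")) epochs <- list(epochs)
    if (is.list(epochs) &&
        all(vapply(epochs, is, logical(1), "StimulusEpoch"))) {
        return(S4Vectors::DataFrame(
            stimulus = vapply(epochs, slot, character(1), "stimulus"),
            concentration_mM = vapply(epochs, slot, numeric(1),
                "concentration"),
            start_s = vapply(epochs, slot, numeric(1), "start"),
            end_s = vapply(epochs, slot, numeric(1), "end")))
    }
    stop("'epochs' must be a DataFrame/data.frame or list of StimulusEpoch")
}

setValidity("TasteTraceSet", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!("ratio" %in% an) && !all(c("f340", "f380") %in% an))
        msg <- c(msg, "need a 'ratio' assay or both 'f340' and 'f380'")
    rd <- SummarizedExperiment::rowData(object)
    if (!("time_s" %in% colnames(rd))) {
        msg <- c(msg, "rowData must contain 'time_s'")
    } else {
        tm <- rd$time_s
        if (length(tm) < 2L) {
            msg <- c(msg, "need at least 2 time points")
        } else {
            dt <- diff(tm)
            if (any(dt <= 0))
                msg <- c(msg, "'time_s' must be strictly increasing")
            else if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
                msg <- c(msg, "'time_s' must be uniformly spaced")
        }
    }
    ep <- S4Vectors::metadata(object)$epochs
    if (!is.null(ep)) {
        need <- c("stimulus", "concentration_mM", "start_s", "end_s")
        if (!all(need %in% colnames(ep))) {
            msg <- c(msg, paste("epochs need columns",
                paste(need, collapse = ", ")))
        } else if (!length(msg)) {
            tm <- SummarizedExperiment::rowData(object)$time_s
            if (any(ep$start_s >= ep$end_s))
                msg <- c(msg, "epoch start_s must be < end_s")
            if (any(ep$start_s < tm[1]) || any(ep$end_s > tm[length(tm)]))
                msg <- c(msg, "epochs must lie within the trace time span")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @rdname TasteTraceSet-class
#' @export
TasteTraceSet <- function(ratio = NULL, f340 = NULL, f380 = NULL,
        time, epochs = NULL, colData = NULL) {
    assays <- list()
    if (!is.null(ratio)) assays$ratio <- as.matrix(ratio)
    if (!is.null(f340)) assays$f340 <- as.matrix(f340)
    if (!is.null(f380)) assays$f380 <- as.matrix(f380)
    if (!length(assays))
        stop("supply 'ratio' or both 'f340' and 'f380'")
    ncells <- ncol(assays[[1]])
    if (is.null(colData))
        colData <- S4Vectors::DataFrame(
            cell_id = paste0("cell", seq_len(ncells)))
    if (is.null(colnames(assays[[1]])))
        assays <- lapply(assays, function(a) {
            colnames(a) <- colData$cell_id
            a
        })
    md <- list()
    if (!is.null(epochs)) md$epochs <- .epochsToDataFrame(epochs)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays,
        rowData = S4Vectors::DataFrame(time_s = as.numeric(time)),
        colData = colData, metadata = md)
    new("TasteTraceSet", se)
}

#' @rdname TasteTraceSet-class
#' @param x a \code{TasteTraceSet}.
#' @param ... unused.
#' @export
setMethod("epochs", "TasteTraceSet", function(x, ...) {
    S4Vectors::metadata(x)$epochs
})

#' @rdname TasteTraceSet-class
#' @param value replacement epochs.
#' @export
setReplaceMethod("epochs", "TasteTraceSet", function(x, value) {
    S4Vectors::metadata(x)$epochs <- .epochsToDataFrame(value)
    validObject(x)
    x
})

#' @rdname TasteTraceSet-class
#' @export
setMethod("traceTimes", "TasteTraceSet", function(x) {
    SummarizedExperiment::rowData(x)$time_s
})

#' @rdname TasteTraceSet-class
#' @export
setMethod("samplingInterval", "TasteTraceSet", function(x) {
    tm <- traceTimes(x)
    (tm[length(tm)] - tm[1]) / (length(tm) - 1L)
})

#' @rdname TasteTraceSet-class
#' @export
setMethod("groundTruth", "TasteTraceSet", function(x) {
    cd <- SummarizedExperiment::colData(x)
    cd[, grepl("^(cell_id|group|true_)", colnames(cd)), drop = FALSE]
})

#' @rdname TasteTraceSet-class
#' @export
setMethod("computeRatio", "TasteTraceSet", function(x, ...) {
    an <- SummarizedExperiment::assayNames(x)
    if ("ratio" %in% an) return(x)
    f340 <- SummarizedExperiment::assay(x, "f340")
    f380 <- SummarizedExperiment::assay(x, "f380")
    bad <- which(f380 <= 0)
    if (length(bad))
        stop(sprintf("f380 must be > 0 everywhere; first offending sample %d",
            bad[1]))
    SummarizedExperiment::assay(x, "ratio") <- f340 / f380
    x
})

setMethod("show", "TasteTraceSet", function(object) {
    tm <- traceTimes(object)
    cat(sprintf("TasteTraceSet: %d cells, %d frames (%g-%g s, dt %g s)\n",
        ncol(object), nrow(object), tm[1], tm[length(tm)],
        samplingInterval(object)))
    cat("  assays:",
        paste(SummarizedExperiment::assayNames(object), collapse = ", "),
        "\n")
    ep <- epochs(object)
    if (!is.null(ep))
        cat("  epochs:", paste(sprintf("%s %g mM @%g-%g s", ep$stimulus,
            ep$concentration_mM, ep$start_s, ep$end_s), collapse = "; "),
            "\n")
    cd <- SummarizedExperiment::colData(object)
    cat("  colData:", paste(colnames(cd), collapse = ", "), "\n")
})
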