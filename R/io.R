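# Plain-text interchange: long-format trace CSVs with an epoch sidecar,
# and intake CSVs.

#' Write and read trace sets as long-format CSV
#'
#' Traces are written one sample per row (\code{cell_id}, \code{time_s},
#' then \code{ratio} or \code{f340}/\code{f380}) with a sidecar epochs
#' file (\code{cell_id}, \code{stimulus}, \code{concentration_mM},
#' \code{start_s}, \code{end_s}). On reading, all cells must share the
#' same time grid and epoch layout (the container keeps one epochs table
#' for the whole set).
#'
#' @param x a \linkS4class{TasteTraceSet}.
#' @param tracesFile,epochsFile CSV paths.
#' @return \code{writeTraces()}: the paths, invisibly;
#'   \code{readTraces()}: a \linkS4class{TasteTraceSet}.
#' @export
writeTraces <- function(x, tracesFile, epochsFile) {
    stopifnot(is(x, "TasteTraceSet"))
    tm <- traceTimes(x)
    an <- SummarizedExperiment::assayNames(x)
    chans <- intersect(c("ratio", "f340", "f380"), an)
    cd <- SummarizedExperiment::colData(x)
    long <- do.call(rbind, lapply(seq_len(ncol(x)), function(i) {
        d <- data.frame(cell_id = cd$cell_id[i], time_s = tm)
        for (ch in chans)
            d[[ch]] <- SummarizedExperiment::assay(x, ch)[, i]
        d
    }))
    utils::write.csv(long, tracesFile, row.names = FALSE)
    ep <- as.data.frame(epochs(x))
    ep <- do.call(rbind, lapply(cd$cell_id, function(id)
        cbind(cell_id = id, ep)))
    utils::write.csv(ep, epochsFile, row.names = FALSE)
    invisible(c(tracesFile, epochsFile))
}

#' @rdname writeTraces
#' @export
readTraces <- function(tracesFile, epochsFile) {
    long <- utils::read.csv(tracesFile)
    need <- c("cell_id", "time_s")
    if (!all(need %in% colnames(long)))
        stop("trace CSV needs columns cell_id, time_s")
    chans <- intersect(c("ratio", "f340", "f380"), colnames(long))
    if (!("ratio" %in% chans) && !all(c("f340", "f380") %in% chans))
        stop("trace CSV needs a 'ratio' column or both 'f340' and 'f380'")
    cells <- unique(long$cell_id)
    tm <- sort(unique(long$time_s))
    mats <- lapply(chans, function(ch) {
        m <- matrix(NA_real_, length(tm), length(cells),
            dimnames = list(NULL, cells))
        for (id in cells) {
            sub <- long[long$cell_id == id, ]
            if (!identical(sort(sub$time_s), tm))
                stop(sprintf("cell '%s' is not on the shared time grid", id))
            m[, id] <- sub[[ch]][order(sub$time_s)]
        }
        m
    })
    names(mats) <- chans
    ep <- utils::read.csv(epochsFile)
    epl <- split(ep[, setdiff(colnames(ep), "cell_id")], ep$cell_id)
    ref <- epl[[1]]
    rownames(ref) <- NULL
    for (e in epl) {
        rownames(e) <- NULL
        if (!isTRUE(all.equal(e, ref)))
            stop("per-cell epoch layouts differ; all cells must share one layout")
    }
    TasteTraceSet(ratio = mats$ratio, f340 = mats$f340,
        f380 = mats$f380, time = tm, epochs = ref,
        colData = S4Vectors::DataFrame(cell_id = cells))
}

#' Read an intake CSV
#'
#' Validates the two-bottle intake schema (\code{animal_id},
#' \code{group}, \code{stimulus}, \code{concentration_mM},
#' \code{period}, \code{test_intake}, \code{water_intake}).
#'
#' @param file CSV path.
#' @return a data.frame of intake records.
#' @export
readIntake <- function(file) {
    rec <- utils::read.csv(file)
    .checkIntakeSchema(rec)
    rec
}
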