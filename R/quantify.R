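# Trace-level response quantification:
# baseline statistics -> 2-SD detection -> onset/offset localisation ->
# percent amplitude, trapezoidal AUC, duration, no-return exclusion.

#' Detection and quantification settings
#'
#' Bundles every tunable of the trace-level analysis. Defaults:
#' baseline = last 30 s before each epoch; a response requires
#' \code{minRun = 3} consecutive samples more than 2 baseline SDs above
#' the baseline mean, searched from epoch start to \code{postWindow = 60}
#' s past epoch end (responses may keep rising during washout); the
#' response ends at the first \code{returnRun = 5} consecutive samples
#' back within \code{returnBandK = 2} SDs of baseline. \code{sdFloor}
#' keeps thresholding defined on noise-free synthetic traces whose
#' baseline SD is exactly zero. \code{smoothPeak} (off by default) takes
#' the peak from a 3-point moving average instead of the raw trace; it
#' lowers measured amplitudes and is provided only for sensitivity
#' analysis. \code{noReturnPolicy} states which summaries drop responses
#' that never return to baseline: \code{"auc_duration"} (default) keeps
#' them in frequency and amplitude summaries, \code{"all"} drops them
#' everywhere.
#'
#' @param baselineWindow baseline window length (s).
#' @param minRun consecutive supra-threshold samples required.
#' @param thresholdK detection threshold in baseline SDs.
#' @param returnBandK return-band half-width in baseline SDs.
#' @param returnRun consecutive in-band samples ending a response.
#' @param postWindow detection search extension past epoch end (s).
#' @param sdFloor relative floor applied to a zero baseline SD.
#' @param smoothPeak logical; 3-point moving-average peak.
#' @param noReturnPolicy \code{"auc_duration"} or \code{"all"}.
#' @return a list of class \code{"DetectionParams"}.
#' @export
detectionParams <- function(baselineWindow = 30, minRun = 3L,
        thresholdK = 2, returnBandK = 2, returnRun = 5L, postWindow = 60,
        sdFloor = 1e-8, smoothPeak = FALSE,
        noReturnPolicy = c("auc_duration", "all")) {
    stopifnot(baselineWindow > 0, minRun >= 1, thresholdK > 0,
        returnBandK > 0, returnRun >= 1, postWindow >= 0, sdFloor > 0)
    structure(list(baselineWindow = baselineWindow,
        minRun = as.integer(minRun), thresholdK = thresholdK,
        returnBandK = returnBandK, returnRun = as.integer(returnRun),
        postWindow = postWindow, sdFloor = sdFloor,
        smoothPeak = isTRUE(smoothPeak),
        noReturnPolicy = match.arg(noReturnPolicy)),
        class = "DetectionParams")
}

.effectiveSd <- function(baseline, sdFloor = 1e-8) {
    max(baseline$sd, sdFloor * max(1, abs(baseline$mean)))
}

#' Compute the F340/F380 ratio
#'
#' Samplewise fura-2 ratio; errors (reporting the first offending sample)
#' if any F380 value is non-positive. The \linkS4class{TasteTraceSet}
#' method adds a \code{"ratio"} assay and passes through if one already
#' exists.
#'
#' @param x numeric vector of F340 values, or a
#'   \linkS4class{TasteTraceSet} with \code{f340}/\code{f380} assays.
#' @param f380 numeric vector of F380 values.
#' @param ... unused.
#' @return numeric ratio vector (or the augmented trace set).
#' @examples
#' computeRatio(c(2, 4), f380 = c(1, 2))
#' @export
setMethod("computeRatio", "numeric", function(x, f380, ...) {
    if (length(x) != length(f380))
        stop("f340 and f380 must have equal length")
    bad <- which(f380 <= 0)
    if (length(bad))
        stop(sprintf("f380 must be > 0 everywhere; first offending sample %d",
            bad[1]))
    x / f380
})

#' Baseline statistics preceding a stimulus epoch
#'
#' Mean and sample SD (n - 1 denominator) of the ratio over the window
#' \code{[epochStart - windowS, epochStart)}.
#'
#' @param time,ratio the trace (seconds; ratio units).
#' @param epochStart epoch start time (s).
#' @param windowS baseline window length (s).
#' @param minSamples minimum pre-stimulus samples required.
#' @return list of class \code{"BaselineStats"} with elements
#'   \code{mean}, \code{sd}, \code{window}, \code{n}.
#' @examples
#' estimateBaseline(0:9, rep(1.1, 10), epochStart = 10, windowS = 10)
#' @export
estimateBaseline <- function(time, ratio, epochStart, windowS = 30,
        minSamples = 5L) {
    start <- epochStart - windowS
    if (start < time[1] - 1e-9)
        stop(sprintf(
            "baseline window [%g, %g) extends before the trace start (%g)",
            start, epochStart, time[1]))
    idx <- which(time >= start - 1e-9 & time < epochStart - 1e-9)
    if (length(idx) < minSamples)
        stop(sprintf("only %d pre-stimulus samples in the baseline window; need >= %d",
            length(idx), minSamples))
    structure(list(mean = mean(ratio[idx]), sd = stats::sd(ratio[idx]),
        window = c(start, epochStart), n = length(idx)),
        class = "BaselineStats")
}

#' Detect an evoked response by the 2-SD rule
#'
#' A response is called when at least \code{minRun} consecutive samples
#' within \code{[epoch start, epoch end + postWindow]} exceed
#' \code{baseline mean + thresholdK * baseline SD}. Returns the first
#' index of the qualifying run. A zero baseline SD is floored (with a
#' warning) so the threshold stays defined.
#'
#' @param time,ratio the trace.
#' @param epoch a \linkS4class{StimulusEpoch}, or numeric
#'   \code{c(start, end)}.
#' @param baseline a \code{"BaselineStats"} (see [estimateBaseline()]).
#' @param params a [detectionParams()] list.
#' @param searchEndIndex optional last index to search (used to stop one
#'   epoch's analysis before the next epoch's baseline window).
#' @return list with \code{responsive}, \code{crossingIndex} (NA when
#'   non-responsive) and \code{threshold}.
#' @export
detectResponse <- function(time, ratio, epoch, baseline,
        params = detectionParams(), searchEndIndex = length(ratio)) {
    if (is(epoch, "StimulusEpoch")) epoch <- c(epoch@start, epoch@end)
    if (baseline$sd <= 0)
        warning("baseline SD is zero; flooring it for thresholding")
    sdEff <- .effectiveSd(baseline, params$sdFloor)
    thr <- baseline$mean + params$thresholdK * sdEff
    idx <- which(time >= epoch[1] - 1e-9 &
        time <= epoch[2] + params$postWindow + 1e-9)
    idx <- idx[idx <= searchEndIndex]
    if (length(idx) < params$minRun)
        return(list(responsive = FALSE, crossingIndex = NA_integer_,
            threshold = thr))
    above <- ratio[idx] > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= params$minRun)
    if (!length(hit))
        return(list(responsive = FALSE, crossingIndex = NA_integer_,
            threshold = thr))
    first <- ends[hit[1]] - r$lengths[hit[1]] + 1L
    list(responsive = TRUE, crossingIndex = idx[first], threshold = thr)
}

#' Locate the response window (onset and return to baseline)
#'
#' Onset is the last sample at or below the baseline mean before the
#' threshold-crossing run, operationalising the initial change in
#' baseline calcium. The offset is the first post-peak sample from which
#' the trace stays within \code{baseline mean +/- returnBandK * SD} for
#' \code{returnRun} consecutive samples; if the trace never settles back
#' before \code{searchEndIndex}, the no-return flag is set (a value, not
#' an error).
#'
#' @inheritParams detectResponse
#' @param crossingIndex first index of the detection run.
#' @return list with \code{onsetIndex}, \code{offsetIndex},
#'   \code{peakIndex}, \code{onset_s}, \code{offset_s}, \code{noReturn}.
#' @export
locateResponseWindow <- function(time, ratio, baseline, crossingIndex,
        params = detectionParams(), searchEndIndex = length(ratio)) {
    sdEff <- .effectiveSd(baseline, params$sdFloor)
    pre <- seq_len(crossingIndex - 1L)
    below <- pre[ratio[pre] <= baseline$mean]
    onsetIndex <- if (length(below)) max(below) else crossingIndex
    span <- crossingIndex:searchEndIndex
    peakIndex <- span[which.max(ratio[span])]
    inBand <- abs(ratio - baseline$mean) <= params$returnBandK * sdEff
    offsetIndex <- NA_integer_
    i <- peakIndex + 1L
    lastStart <- searchEndIndex - params$returnRun + 1L
    while (i <= lastStart) {
        if (all(inBand[i:(i + params$returnRun - 1L)])) {
            offsetIndex <- i
            break
        }
        i <- i + 1L
    }
    noReturn <- is.na(offsetIndex)
    list(onsetIndex = onsetIndex, offsetIndex = offsetIndex,
        peakIndex = peakIndex, onset_s = time[onsetIndex],
        offset_s = if (noReturn) NA_real_ else time[offsetIndex],
        noReturn = noReturn)
}

#' Peak amplitude as percent increase over baseline
#'
#' \code{amplitude_pct = 100 * (peak - baseline mean) / baseline mean},
#' with the peak taken as the maximum ratio in \code{[onset, offset]}
#' (or to the end of the search span for no-return responses).
#'
#' @inheritParams detectResponse
#' @param onsetIndex,offsetIndex the located window;
#'   \code{offsetIndex = NA} means no return (the window runs to
#'   \code{searchEndIndex}).
#' @return list with \code{peak} and \code{amplitude_pct}.
#' @examples
#' b <- structure(list(mean = 1, sd = 0.01), class = "BaselineStats")
#' quantifyAmplitude(0:4, c(1, 1.742, 1.5, 1.2, 1), b, 1, 5)$amplitude_pct
#' @export
quantifyAmplitude <- function(time, ratio, baseline, onsetIndex,
        offsetIndex, params = detectionParams(),
        searchEndIndex = length(ratio)) {
    if (baseline$mean <= 0)
        stop("baseline mean must be > 0 to express amplitude in percent")
    stopIdx <- if (is.na(offsetIndex)) searchEndIndex else offsetIndex
    y <- ratio
    if (params$smoothPeak)
        y <- as.numeric(stats::filter(ratio, rep(1 / 3, 3), sides = 2))
    win <- onsetIndex:stopIdx
    peak <- max(y[win], na.rm = TRUE)
    list(peak = peak,
        amplitude_pct = 100 * (peak - baseline$mean) / baseline$mean)
}

#' Integrate the response above baseline
#'
#' Trapezoidal integral of \code{max(ratio - baseline mean, 0)} over
#' \code{[onset, offset]}; excursions below baseline contribute zero.
#' Responses that never return to baseline are excluded upstream and must
#' not be integrated.
#'
#' @inheritParams quantifyAmplitude
#' @return the area under the curve (ratio x s).
#' @export
integrateResponse <- function(time, ratio, baseline, onsetIndex,
        offsetIndex) {
    if (is.na(offsetIndex) || offsetIndex <= onsetIndex)
        stop("need a located window with offset after onset")
    win <- onsetIndex:offsetIndex
    y <- pmax(ratio[win] - baseline$mean, 0)
    tt <- time[win]
    sum(diff(tt) * (y[-1] + y[-length(y)]) / 2)
}

.emptyCall <- function(cell_id, stimulus, concentration, baseline) {
    data.frame(cell_id = cell_id, stimulus = stimulus,
        concentration_mM = concentration, responsive = FALSE,
        baseline_mean = baseline$mean, baseline_sd = baseline$sd,
        peak = NA_real_, amplitude_pct = NA_real_, onset_s = NA_real_,
        offset_s = NA_real_, auc = NA_real_, duration_s = NA_real_,
        excluded_no_return = FALSE, stringsAsFactors = FALSE)
}

#' Quantify one cell across all of its stimulus epochs
#'
#' Runs the full per-epoch analysis -- baseline estimation over the
#' window immediately preceding each epoch, 2-SD detection,
#' onset/offset localisation, amplitude, AUC and duration -- and returns
#' one row per epoch. Epochs are analysed independently; each epoch's
#' search span is capped where the next epoch's baseline window begins.
#' Responses that never return to baseline get \code{excluded_no_return
#' = TRUE} with \code{auc} and \code{duration_s} set to \code{NA}.
#'
#' @param time,ratio the trace.
#' @param epochs a \code{DataFrame}/\code{data.frame} of epochs (columns
#'   \code{stimulus}, \code{concentration_mM}, \code{start_s},
#'   \code{end_s}), or a list of \linkS4class{StimulusEpoch}.
#' @param params a [detectionParams()] list.
#' @param cell_id identifier stamped on the rows.
#' @return a data.frame, one row per epoch.
#' @export
quantifyCell <- function(time, ratio, epochs, params = detectionParams(),
        cell_id = "cell1") {
    ep <- as.data.frame(.epochsToDataFrame(epochs))
    ep <- ep[order(ep$start_s), , drop = FALSE]
    if (nrow(ep) > 1L &&
        any(ep$start_s[-1] < ep$end_s[-nrow(ep)]))
        stop("stimulus epochs overlap")
    out <- vector("list", nrow(ep))
    for (k in seq_len(nrow(ep))) {
        segEnd <- if (k < nrow(ep)) {
            nextBase <- ep$start_s[k + 1L] - params$baselineWindow
            max(which(time < nextBase - 1e-9))
        } else length(ratio)
        baseline <- estimateBaseline(time, ratio, ep$start_s[k],
            windowS = params$baselineWindow)
        call <- .emptyCall(cell_id, ep$stimulus[k],
            ep$concentration_mM[k], baseline)
        det <- detectResponse(time, ratio,
            c(ep$start_s[k], ep$end_s[k]), baseline, params,
            searchEndIndex = segEnd)
        if (det$responsive) {
            loc <- locateResponseWindow(time, ratio, baseline,
                det$crossingIndex, params, searchEndIndex = segEnd)
            amp <- quantifyAmplitude(time, ratio, baseline,
                loc$onsetIndex, loc$offsetIndex, params,
                searchEndIndex = segEnd)
            call$responsive <- TRUE
            call$peak <- amp$peak
            call$amplitude_pct <- amp$amplitude_pct
            call$onset_s <- loc$onset_s
            call$offset_s <- loc$offset_s
            call$excluded_no_return <- loc$noReturn
            if (!loc$noReturn) {
                call$auc <- integrateResponse(time, ratio, baseline,
                    loc$onsetIndex, loc$offsetIndex)
                call$duration_s <- loc$offset_s - loc$onset_s
            }
        }
        out[[k]] <- call
    }
    do.call(rbind, out)
}

#' Quantify every cell of a trace set
#'
#' Applies [quantifyCell()] to each column of a
#' \linkS4class{TasteTraceSet} (computing the ratio first if only raw
#' channels are present) and returns the combined response-call table.
#' Cohort labels from \code{colData(x)$group} are carried through.
#'
#' @param x a \linkS4class{TasteTraceSet} with an epochs table.
#' @param params a [detectionParams()] list.
#' @return a \code{DataFrame}, one row per cell x stimulus, with the
#'   columns documented in [quantifyCell()] plus \code{group}.
#' @examples
#' cfg <- cohortConfig("ctl", list(SAC = tracePreset("ctl_SAC")),
#'     nCells = 3)
#' calls <- quantifyCells(simulateCohort(cfg, seed = 1))
#' calls[, c("cell_id", "stimulus", "responsive", "amplitude_pct")]
#' @export
quantifyCells <- function(x, params = detectionParams()) {
    stopifnot(is(x, "TasteTraceSet"))
    if (is.null(epochs(x)))
        stop("trace set has no epochs table")
    x <- computeRatio(x)
    tm <- traceTimes(x)
    ratio <- SummarizedExperiment::assay(x, "ratio")
    cd <- SummarizedExperiment::colData(x)
    grp <- if ("group" %in% colnames(cd)) cd$group else
        rep(NA_character_, ncol(x))
    ep <- epochs(x)
    out <- lapply(seq_len(ncol(x)), function(i) {
        calls <- quantifyCell(tm, ratio[, i], ep, params,
            cell_id = cd$cell_id[i])
        calls$group <- grp[i]
        calls
    })
    S4Vectors::DataFrame(do.call(rbind, out))
}
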