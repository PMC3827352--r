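# KCl-based cell typing: cells responding to 50 mM KCl are presumed to
# express voltage-gated calcium channels (presumptive Type III); umami
# (MPG) analysis is restricted to KCl-non-responders because MPG's
# potassium content could itself depolarise Type III cells.

#' Per-cell profiles and KCl-based type inference
#'
#' Collapses a response-call table to one row per cell, recording KCl
#' responsiveness and the inferred cell type: KCl-responsive cells are
#' \code{"presumptive_TypeIII"}, KCl-tested non-responders
#' \code{"presumptive_TypeII"}, and cells never tested with KCl
#' \code{"undetermined"}.
#'
#' @param calls a response-call table from [quantifyCells()].
#' @param kclStimulus name of the depolarisation stimulus.
#' @return a \code{DataFrame} with columns \code{cell_id}, \code{group},
#'   \code{kcl_responsive}, \code{inferred_type}.
#' @examples
#' cfg <- cohortConfig("ctl",
#'     list(MPG = tracePreset("ctl_MPG"), KCl = tracePreset("kcl")),
#'     nCells = 3, kclPositiveFraction = 0.5)
#' cellProfiles(quantifyCells(simulateCohort(cfg, seed = 1)))
#' @export
cellProfiles <- function(calls, kclStimulus = "KCl") {
    calls <- as.data.frame(calls)
    ids <- unique(calls$cell_id)
    kcl <- calls[calls$stimulus == kclStimulus, , drop = FALSE]
    kclResp <- kcl$responsive[match(ids, kcl$cell_id)]
    grp <- calls$group[match(ids, calls$cell_id)]
    S4Vectors::DataFrame(cell_id = ids, group = grp,
        kcl_responsive = kclResp,
        inferred_type = classifyCell(kclResp))
}

#' Classify cells by KCl responsiveness
#'
#' @param kclResponsive logical vector; \code{NA} means the cell was
#'   never tested with KCl.
#' @return character vector: \code{"presumptive_TypeIII"} (responsive),
#'   \code{"presumptive_TypeII"} (tested, non-responsive) or
#'   \code{"undetermined"} (untested).
#' @examples
#' classifyCell(c(TRUE, FALSE, NA))
#' @export
classifyCell <- function(kclResponsive) {
    ifelse(is.na(kclResponsive), "undetermined",
        ifelse(kclResponsive, "presumptive_TypeIII",
            "presumptive_TypeII"))
}

#' Restrict MPG calls to presumptive Type II cells
#'
#' Returns the MPG response calls from cells that were tested with KCl
#' and did not respond; calls from KCl-responsive or KCl-untested cells
#' are dropped (with a message / warning reporting how many), since
#' their MPG responses could reflect potassium-driven depolarisation
#' rather than umami transduction.
#'
#' @param calls a response-call table from [quantifyCells()].
#' @param profiles optional precomputed [cellProfiles()] table.
#' @param stimulus the umami stimulus name.
#' @return the filtered subset of \code{calls}.
#' @export
selectUmamiResponses <- function(calls, profiles = cellProfiles(calls),
        stimulus = "MPG") {
    df <- as.data.frame(calls)
    mpg <- df[df$stimulus == stimulus, , drop = FALSE]
    prof <- as.data.frame(profiles)
    kcl <- prof$kcl_responsive[match(mpg$cell_id, prof$cell_id)]
    nUntested <- sum(is.na(kcl))
    nTypeIII <- sum(kcl, na.rm = TRUE)
    if (nUntested)
        warning(sprintf(
            "%d cell(s) without a KCl test excluded from the umami analysis",
            nUntested))
    if (nTypeIII)
        message(sprintf(
            "%d KCl-responsive (presumptive Type III) cell(s) excluded from the umami analysis",
            nTypeIII))
    keep <- !is.na(kcl) & !kcl
    calls[calls$stimulus == stimulus, , drop = FALSE][keep, , drop = FALSE]
}
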