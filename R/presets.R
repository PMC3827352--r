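# Packaged trace presets.
#
# Mean amplitudes (% over baseline) are the published cohort means for
# each stimulus (control, obese-male, obese-female); the pooled-obese
# denatonium preset takes the mean of the two sex values because no
# pooled amplitude is published. Denatonium target durations are the
# published means (control 50.5 s, obese 65.5 s); the remaining stimuli
# have no published duration and use 50 s. 'ctl_ACEK_AUC' anchors the
# amplitude at the published control AceK mean and calibrates the decay
# so the noise-free integral equals the published AUC of 29.2 ratio*s,
# which implies a long slow decay and hence a longer trace.

.PRESET_TABLE <- data.frame(
    name = c("ctl_SAC", "obM_SAC", "obF_SAC",
             "ctl_ACEK", "obM_ACEK", "obF_ACEK",
             "ctl_MPG", "obM_MPG", "obF_MPG",
             "ctl_DEN", "obM_DEN", "obF_DEN", "ob_DEN",
             "ctl_ACEK_AUC", "kcl"),
    stimulus = c("SAC", "SAC", "SAC",
                 "AceK", "AceK", "AceK",
                 "MPG", "MPG", "MPG",
                 "Den", "Den", "Den", "Den",
                 "AceK", "KCl"),
    concentration_mM = c(2, 2, 2, 20, 20, 20, 20, 20, 20,
                         5, 5, 5, 5, 20, 50),
    amplitude_pct = c(74.2, 19.1, 8.2,
                      37.8, 21.1, 7.9,
                      18.6, 15.7, 17,
                      59.8, 12.4, 22.1, (12.4 + 22.1) / 2,
                      37.8, 30),
    target_duration_s = c(50, 50, 50, 50, 50, 50, 50, 50, 50,
                          50.5, 50, 50, 65.5, NA, 40),
    target_auc = c(rep(NA, 13), 29.2, NA),
    duration_total_s = c(rep(240, 13), 420, 240),
    stringsAsFactors = FALSE)

#' Packaged trace presets
#'
#' \code{tracePresets()} lists the packaged presets; \code{tracePreset()}
#' builds the corresponding \linkS4class{TraceGenParams}. Preset names
#' combine a cohort (\code{ctl}, \code{obM}, \code{obF}, pooled
#' \code{ob}) with a stimulus (\code{SAC} 2 mM, \code{ACEK} 20 mM,
#' \code{MPG} 20 mM, \code{DEN} 5 mM); \code{"kcl"} is the 50 mM KCl
#' depolarisation control used for cell typing. Mean amplitudes are the
#' published cohort means; decay constants are calibrated with
#' [calibrateDecay()] to the preset's target duration, except
#' \code{"ctl_ACEK_AUC"} whose decay comes from [calibrateAucDecay()] so
#' that the noise-free response integral equals the published control
#' AceK area under the curve.
#'
#' @param name preset name, one of \code{tracePresets()$name}.
#' @param noiseSd,baselineMean,riseTau,onsetLatency,samplingInterval
#'   generator settings shared by all presets; see
#'   \linkS4class{TraceGenParams}.
#' @param returnBandK return-band half-width (baseline SDs) used in the
#'   duration/AUC calibration; keep equal to the analysis setting in
#'   [detectionParams()].
#' @return \code{tracePreset()}: a \linkS4class{TraceGenParams};
#'   \code{tracePresets()}: a data.frame of preset definitions.
#' @examples
#' tracePresets()
#' tracePreset("ctl_SAC")
#' @export
tracePreset <- function(name, noiseSd = 0.005, baselineMean = 1,
        riseTau = 2, onsetLatency = 2, samplingInterval = 1,
        returnBandK = 2) {
    row <- .PRESET_TABLE[.PRESET_TABLE$name == name, ]
    if (!nrow(row))
        stop(sprintf("unknown preset '%s'; see tracePresets()", name))
    decayTau <- if (!is.na(row$target_auc))
        calibrateAucDecay(row$amplitude_pct, baselineMean, noiseSd,
            targetAuc = row$target_auc, returnBandK = returnBandK,
            riseTau = riseTau)
    else
        calibrateDecay(row$amplitude_pct, baselineMean, noiseSd,
            targetDuration = row$target_duration_s,
            returnBandK = returnBandK, riseTau = riseTau)
    TraceGenParams(baselineMean = baselineMean, noiseSd = noiseSd,
        responder = TRUE, amplitudePct = row$amplitude_pct,
        riseTau = riseTau, decayTau = decayTau,
        onsetLatency = onsetLatency,
        samplingInterval = samplingInterval,
        durationTotal = row$duration_total_s,
        epoch = StimulusEpoch(row$stimulus, row$concentration_mM,
            start = 60, end = 90))
}

#' @rdname tracePreset
#' @export
tracePresets <- function() .PRESET_TABLE
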