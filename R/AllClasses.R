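#' Stimulus application epoch
#'
#' Describes one bath application of a taste stimulus within a trace:
#' the stimulus name (e.g. \code{"SAC"}, \code{"AceK"}, \code{"MPG"},
#' \code{"Den"}, \code{"KCl"}), its concentration in mM, and the start/end
#' of the application window in seconds on the trace-local clock (zero at
#' the first frame).
#'
#' @slot stimulus character(1), stimulus name.
#' @slot concentration numeric(1), concentration in mM.
#' @slot start numeric(1), application start (s).
#' @slot end numeric(1), application end (s).
#'
#' @examples
#' StimulusEpoch("SAC", 2, start = 60, end = 90)
#' @export
setClass("StimulusEpoch",
    representation(
        stimulus = "character",
        concentration = "numeric",
        start = "numeric",
        end = "numeric"
    )
)

setValidity("StimulusEpoch", function(object) {
    msg <- character()
    if (length(object@stimulus) != 1L || !nzchar(object@stimulus))
        msg <- c(msg, "'stimulus' must be a single non-empty string")
    if (length(object@concentration) != 1L || is.na(object@concentration) ||
        object@concentration < 0)
        msg <- c(msg, "'concentration' must be a single non-negative number")
    if (length(object@start) != 1L || length(object@end) != 1L ||
        !is.finite(object@start) || !is.finite(object@end))
        msg <- c(msg, "'start' and 'end' must be single finite numbers")
    else if (object@start >= object@end)
        msg <- c(msg, "'start' must be strictly less than 'end'")
    if (length(msg)) msg else TRUE
})

#' @rdname StimulusEpoch-class
#' @param stimulus,concentration,start,end see slots.
#' @export
StimulusEpoch <- function(stimulus, concentration, start, end) {
    new("StimulusEpoch", stimulus = as.character(stimulus),
        concentration = as.numeric(concentration),
        start = as.numeric(start), end = as.numeric(end))
}

setMethod("show", "StimulusEpoch", function(object) {
    cat(sprintf("StimulusEpoch: %s %g mM, %g-%g s\n", object@stimulus,
        object@concentration, object@start, object@end))
})

#' Parameters of the synthetic fura-2 trace generator
#'
#' Holds everything needed to simulate one cell's F340/F380 ratio trace:
#' a flat baseline with i.i.d. Gaussian noise and, for responders, an
#' additive stimulus-locked transient with a saturating-exponential rise
#' followed by an exponential decay. The transient starts
#' \code{onsetLatency} seconds after the stimulus epoch begins, reaches
#' its peak -- exactly \code{amplitudePct/100 * baselineMean} above
#' baseline -- \code{5 * riseTau} seconds after transient onset (the rise
#' is normalised so the configured peak is attained exactly), and then
#' decays with time constant \code{decayTau}.
#'
#' @slot baselineMean baseline F340/F380 ratio (dimensionless; the scale
#'   is arbitrary because all downstream measures are relative).
#' @slot noiseSd standard deviation of the additive Gaussian noise, in
#'   ratio units.
#' @slot responder logical(1); non-responders are baseline plus noise only.
#' @slot amplitudePct true peak amplitude as percent increase over baseline.
#' @slot riseTau,decayTau rise and decay time constants (s).
#' @slot onsetLatency delay from epoch start to transient onset (s).
#' @slot samplingInterval frame interval (s).
#' @slot durationTotal total trace duration (s).
#' @slot driftPerS optional linear baseline drift (ratio units per s,
#'   default 0); used to stress-test baseline estimation.
#' @slot epoch a \linkS4class{StimulusEpoch}.
#'
#' @seealso [simulateTrace()], [tracePreset()], [calibrateDecay()]
#' @export
setClass("TraceGenParams",
    representation(
        baselineMean = "numeric",
        noiseSd = "numeric",
        responder = "logical",
        amplitudePct = "numeric",
        riseTau = "numeric",
        decayTau = "numeric",
        onsetLatency = "numeric",
        samplingInterval = "numeric",
        durationTotal = "numeric",
        driftPerS = "numeric",
        epoch = "StimulusEpoch"
    )
)

setValidity("TraceGenParams", function(object) {
    msg <- character()
    chk1 <- function(x) length(x) == 1L && is.finite(x)
    if (!chk1(object@baselineMean) || object@baselineMean <= 0)
        msg <- c(msg, "'baselineMean' must be a single positive number")
    if (!chk1(object@noiseSd) || object@noiseSd <= 0)
        msg <- c(msg, "'noiseSd' must be > 0")
    if (length(object@responder) != 1L || is.na(object@responder))
        msg <- c(msg, "'responder' must be TRUE or FALSE")
    if (!chk1(object@amplitudePct) || object@amplitudePct < 0)
        msg <- c(msg, "'amplitudePct' must be >= 0")
    if (!chk1(object@riseTau) || object@riseTau <= 0)
        msg <- c(msg, "'riseTau' must be > 0")
    if (!chk1(object@decayTau) || object@decayTau <= 0)
        msg <- c(msg, "'decayTau' must be > 0")
    if (!chk1(object@onsetLatency) || object@onsetLatency < 0)
        msg <- c(msg, "'onsetLatency' must be >= 0")
    if (!chk1(object@samplingInterval) || object@samplingInterval <= 0)
        msg <- c(msg, "'samplingInterval' must be > 0")
    if (!chk1(object@durationTotal) || object@durationTotal <= 0)
        msg <- c(msg, "'durationTotal' must be > 0")
    if (!chk1(object@driftPerS))
        msg <- c(msg, "'driftPerS' must be a single finite number")
    if (!length(msg)) {
        if (object@epoch@end > object@durationTotal ||
            object@epoch@start < 0)
            msg <- c(msg,
                "'epoch' must lie within [0, durationTotal]")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname TraceGenParams-class
#' @param baselineMean,noiseSd,responder,amplitudePct,riseTau,decayTau
#'   see slots.
#' @param onsetLatency,samplingInterval,durationTotal,driftPerS,epoch
#'   see slots.
#' @export
TraceGenParams <- function(baselineMean = 1.0, noiseSd = 0.005,
        responder = TRUE, amplitudePct = 50, riseTau = 2, decayTau = 10,
        onsetLatency = 2, samplingInterval = 1, durationTotal = 240,
        driftPerS = 0,
        epoch = StimulusEpoch("custom", 0, start = 60, end = 90)) {
    new("TraceGenParams", baselineMean = baselineMean, noiseSd = noiseSd,
        responder = responder, amplitudePct = amplitudePct,
        riseTau = riseTau, decayTau = decayTau, onsetLatency = onsetLatency,
        samplingInterval = samplingInterval, durationTotal = durationTotal,
        driftPerS = driftPerS, epoch = epoch)
}

setMethod("show", "TraceGenParams", function(object) {
    cat("TraceGenParams\n")
    cat(sprintf("  baseline %g, noise sd %g, %s\n", object@baselineMean,
        object@noiseSd,
        if (object@responder) sprintf("responder (%.1f%% peak)",
            object@amplitudePct) else "non-responder"))
    cat(sprintf("  rise tau %g s, decay tau %g s, onset latency %g s\n",
        object@riseTau, object@decayTau, object@onsetLatency))
    cat(sprintf("  %g s at %g s/frame; epoch %s %g mM %g-%g s\n",
        object@durationTotal, object@samplingInterval,
        object@epoch@stimulus, object@epoch@concentration,
        object@epoch@start, object@epoch@end))
})

#' Configuration of a synthetic imaging cohort
#'
#' Describes one diet-by-sex cohort: how many cells to simulate, the
#' per-stimulus trace presets, the per-stimulus responder fractions, the
#' fraction of KCl-positive (presumptive Type III) cells, and the
#' between-cell amplitude heterogeneity (lognormal coefficient of
#' variation around each preset's mean amplitude; set to 0 for fixed
#' amplitudes).
#'
#' The stimulus epochs of the supplied presets are re-laid sequentially
#' (one segment per stimulus) by [cohortConfig()], so one simulated cell
#' is a single long trace containing one epoch per stimulus.
#'
#' @slot label cohort label, e.g. \code{"ctl"}, \code{"obM"}, \code{"obF"}.
#' @slot nCells number of cells.
#' @slot presets named list of \linkS4class{TraceGenParams}, one per
#'   stimulus (names are stimulus names).
#' @slot responderFraction named numeric in [0,1], one entry per stimulus.
#' @slot kclPositiveFraction probability a cell responds to KCl; used for
#'   the \code{"KCl"} stimulus when present (overrides its entry in
#'   \code{responderFraction}).
#' @slot amplitudeCv lognormal CV of per-cell true amplitudes.
#' @export
setClass("CohortConfig",
    representation(
        label = "character",
        nCells = "integer",
        presets = "list",
        responderFraction = "numeric",
        kclPositiveFraction = "numeric",
        amplitudeCv = "numeric"
    )
)

setValidity("CohortConfig", function(object) {
    msg <- character()
    if (length(object@label) != 1L || !nzchar(object@label))
        msg <- c(msg, "'label' must be a single non-empty string")
    if (length(object@nCells) != 1L || is.na(object@nCells) ||
        object@nCells < 1L)
        msg <- c(msg, "'nCells' must be >= 1")
    if (!length(object@presets) ||
        !all(vapply(object@presets, is, logical(1), "TraceGenParams")))
        msg <- c(msg, "'presets' must be a non-empty list of TraceGenParams")
    nm <- names(object@presets)
    if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
        msg <- c(msg, "'presets' must have unique stimulus names")
    frac <- object@responderFraction
    if (!all(nm %in% names(frac)))
        msg <- c(msg, "'responderFraction' must name every stimulus")
    if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1))
        msg <- c(msg, "'responderFraction' entries must be in [0, 1]")
    if (length(object@kclPositiveFraction) != 1L ||
        !is.finite(object@kclPositiveFraction) ||
        object@kclPositiveFraction < 0 || object@kclPositiveFraction > 1)
        msg <- c(msg, "'kclPositiveFraction' must be in [0, 1]")
    if (length(object@amplitudeCv) != 1L ||
        !is.finite(object@amplitudeCv) || object@amplitudeCv < 0)
        msg <- c(msg, "'amplitudeCv' must be >= 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CohortConfig", function(object) {
    cat(sprintf("CohortConfig '%s': %d cells, stimuli %s\n", object@label,
        object@nCells, paste(names(object@presets), collapse = ", ")))
    cat("  responder fractions:",
        paste(sprintf("%s=%.2f", names(object@presets),
            object@responderFraction[names(object@presets)]),
            collapse = ", "), "\n")
    cat(sprintf("  KCl-positive fraction %.2f, amplitude CV %.2f\n",
        object@kclPositiveFraction, object@amplitudeCv))
})

#' Parameters of the two-bottle intake generator
#'
#' @slot truePreference expected test-solution share of total intake;
#'   either a single value or one per concentration.
#' @slot dailyTotalMean,dailyTotalSd mean and SD of an animal's 24 h total
#'   fluid intake (mL); draws are truncated at zero.
#' @slot nAnimals animals per group.
#' @slot concentrations ascending concentration series (mM).
#' @slot nPeriods number of 24 h periods per concentration (2 = 48 h with
#'   one side swap).
#' @slot betaPrecision precision of the beta-distributed animal-level
#'   preference noise (larger = less noise; \code{Inf} disables it).
#' @slot sideBias additive intake bias toward the left bottle position,
#'   on the preference-share scale; used to verify that the 24 h side
#'   swap cancels positional preferences.
#' @slot stimulus,group labels stamped on the generated records.
#' @export
setClass("IntakeGenParams",
    representation(
        truePreference = "numeric",
        dailyTotalMean = "numeric",
        dailyTotalSd = "numeric",
        nAnimals = "integer",
        concentrations = "numeric",
        nPeriods = "integer",
        betaPrecision = "numeric",
        sideBias = "numeric",
        stimulus = "character",
        group = "character"
    )
)

setValidity("IntakeGenParams", function(object) {
    msg <- character()
    p <- object@truePreference
    if (!length(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
        msg <- c(msg, "'truePreference' must be in [0, 1]")
    if (length(p) != 1L && length(p) != length(object@concentrations))
        msg <- c(msg,
            "'truePreference' must have length 1 or one entry per concentration")
    if (length(object@dailyTotalMean) != 1L || object@dailyTotalMean <= 0)
        msg <- c(msg, "'dailyTotalMean' must be > 0")
    if (length(object@dailyTotalSd) != 1L || object@dailyTotalSd < 0)
        msg <- c(msg, "'dailyTotalSd' must be >= 0")
    if (length(object@nAnimals) != 1L || object@nAnimals < 1L)
        msg <- c(msg, "'nAnimals' must be >= 1")
    if (!length(object@concentrations) ||
        is.unsorted(object@concentrations, strictly = TRUE))
        msg <- c(msg, "'concentrations' must be strictly ascending")
    if (length(object@nPeriods) != 1L || object@nPeriods < 1L)
        msg <- c(msg, "'nPeriods' must be >= 1")
    if (length(object@betaPrecision) != 1L || object@betaPrecision <= 0)
        msg <- c(msg, "'betaPrecision' must be > 0 (Inf allowed)")
    if (length(object@sideBias) != 1L || !is.finite(object@sideBias))
        msg <- c(msg, "'sideBias' must be a single finite number")
    if (length(msg)) msg else TRUE
})

#' @rdname IntakeGenParams-class
#' @param truePreference,dailyTotalMean,dailyTotalSd,nAnimals see slots.
#' @param concentrations,nPeriods,betaPrecision,sideBias,stimulus,group
#'   see slots.
#' @export
IntakeGenParams <- function(truePreference = 0.5, dailyTotalMean = 6,
        dailyTotalSd = 1, nAnimals = 5L, concentrations = c(1, 2, 10, 20),
        nPeriods = 2L, betaPrecision = 50, sideBias = 0,
        stimulus = "SAC", group = "ctl") {
    new("IntakeGenParams", truePreference = as.numeric(truePreference),
        dailyTotalMean = dailyTotalMean, dailyTotalSd = dailyTotalSd,
        nAnimals = as.integer(nAnimals),
        concentrations = as.numeric(concentrations),
        nPeriods = as.integer(nPeriods), betaPrecision = betaPrecision,
        sideBias = sideBias, stimulus = stimulus, group = group)
}

setMethod("show", "IntakeGenParams", function(object) {
    cat(sprintf(
        "IntakeGenParams '%s'/'%s': %d animals, %d x 24 h, %s mM\n",
        object@group, object@stimulus, object@nAnimals, object@nPeriods,
        paste(object@concentrations, collapse = "/")))
    cat(sprintf("  preference %s, total %g +/- %g mL/24 h\n",
        paste(round(object@truePreference, 3), collapse = "/"),
        object@dailyTotalMean, object@dailyTotalSd))
})
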