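# Synthetic fura-2-like trace generation.
#
# The evoked transient is an additive bump on a flat baseline:
# a saturating-exponential rise lasting 5*riseTau (normalised so the
# configured peak is attained exactly at the end of the rise), followed
# by a single-exponential decay. The peak falls on the sampling grid
# whenever onset and 5*riseTau are multiples of the sampling interval,
# which all packaged presets satisfy.

.RISE_MULT <- 5

# deterministic per-unit substream seed: stable under cohort-size changes
# and bounded well below 2^31
.subSeed <- function(seed, i) {
    as.integer((as.numeric(seed) %% 1048576) * 2039 + i * 7 + 1) %% 2147483647L
}

# noise-free transient elevation above baseline at times t
.transientDelta <- function(t, t0, peakDelta, riseTau, decayTau) {
    riseDur <- .RISE_MULT * riseTau
    tPeak <- t0 + riseDur
    d <- numeric(length(t))
    ris <- t >= t0 & t <= tPeak
    d[ris] <- peakDelta * (1 - exp(-(t[ris] - t0) / riseTau)) /
        (1 - exp(-.RISE_MULT))
    dec <- t > tPeak
    d[dec] <- peakDelta * exp(-(t[dec] - tPeak) / decayTau)
    d
}

# closed-form integral of the noise-free transient from onset to the
# point where it has decayed to 'band' above baseline
.transientIntegral <- function(peakDelta, riseTau, decayTau, band) {
    r <- .RISE_MULT
    riseInt <- peakDelta *
        (r * riseTau / (1 - exp(-r)) - riseTau)
    decInt <- decayTau * (peakDelta - band)
    riseInt + decInt
}

.traceGrid <- function(params) {
    n <- round(params@durationTotal / params@samplingInterval)
    (seq_len(n) - 1L) * params@samplingInterval
}

.simulateTraceVector <- function(params, seed = NULL,
        amplitudePct = params@amplitudePct) {
    if (!is.null(seed)) set.seed(seed)
    t <- .traceGrid(params)
    y <- params@baselineMean + params@driftPerS * t +
        stats::rnorm(length(t), 0, params@noiseSd)
    if (params@responder && amplitudePct > 0) {
        t0 <- params@epoch@start + params@onsetLatency
        peakDelta <- amplitudePct * params@baselineMean / 100
        y <- y + .transientDelta(t, t0, peakDelta, params@riseTau,
            params@decayTau)
    }
    y
}

#' Simulate a single fura-2-like ratio trace
#'
#' Generates one cell's ratio trace from a \linkS4class{TraceGenParams}:
#' baseline plus i.i.d. Gaussian noise, with an additive evoked transient
#' for responders (see the class documentation for the transient shape).
#' Identical \code{(params, seed)} give a bit-identical trace.
#'
#' @param params a \linkS4class{TraceGenParams}.
#' @param seed integer seed.
#' @return a single-cell \linkS4class{TasteTraceSet} whose colData carries
#'   the ground truth (\code{true_responder}, \code{true_amplitude_pct}).
#' @examples
#' tr <- simulateTrace(TraceGenParams(amplitudePct = 74.2), seed = 1)
#' max(SummarizedExperiment::assay(tr, "ratio"))
#' @export
simulateTrace <- function(params, seed = 0L) {
    stopifnot(is(params, "TraceGenParams"))
    validObject(params)
    y <- .simulateTraceVector(params, seed = seed)
    TasteTraceSet(ratio = matrix(y, ncol = 1),
        time = .traceGrid(params), epochs = params@epoch,
        colData = S4Vectors::DataFrame(cell_id = "cell1",
            true_responder = params@responder,
            true_amplitude_pct = if (params@responder)
                params@amplitudePct else 0))
}

#' Calibrate the decay constant to a target response duration
#'
#' Solves, in closed form, for the decay time constant such that the
#' noise-free transient re-enters the return band
#' \code{baseline +/- returnBandK * noiseSd} exactly
#' \code{targetDuration} seconds after transient onset. With a rise
#' lasting \code{5 * riseTau},
#' \deqn{\tau_{decay} = \frac{T - 5\tau_{rise}}
#'   {\ln(\Delta_{peak} / (k\,\sigma))}}{
#'   decayTau = (T - 5*riseTau) / ln(peakDelta / (k*noiseSd))}
#' where \eqn{\Delta_{peak}} is the peak elevation above baseline.
#' Used to build presets whose pipeline-measured durations land on a
#' stated target (e.g. the denatonium response durations).
#'
#' @param amplitudePct peak amplitude, percent over baseline.
#' @param baselineMean baseline ratio.
#' @param noiseSd noise SD defining the return band.
#' @param targetDuration desired onset-to-return duration (s).
#' @param returnBandK band half-width in baseline SDs.
#' @param riseTau rise time constant (s).
#' @return decay time constant (s).
#' @seealso [calibrateAucDecay()], [tracePreset()]
#' @examples
#' # peak elevation 0.5, band 0.05, 46.05 s after the peak -> tau = 20 s
#' calibrateDecay(50, 1, 0.025, targetDuration = 46.05 + 5 * 2,
#'     returnBandK = 2, riseTau = 2)
#' @export
calibrateDecay <- function(amplitudePct, baselineMean = 1, noiseSd = 0.005,
        targetDuration, returnBandK = 2, riseTau = 2) {
    peakDelta <- amplitudePct * baselineMean / 100
    band <- returnBandK * noiseSd
    if (peakDelta <= band)
        stop(sprintf(
            "infeasible calibration: peak elevation %.4g not above the return band %.4g",
            peakDelta, band))
    riseDur <- .RISE_MULT * riseTau
    if (targetDuration <= riseDur)
        stop(sprintf(
            "infeasible calibration: targetDuration %.4g s must exceed the rise (%g s)",
            targetDuration, riseDur))
    (targetDuration - riseDur) / log(peakDelta / band)
}

#' Calibrate the decay constant to a target response integral
#'
#' Solves for the decay time constant such that the noise-free
#' transient's positive-part integral from onset to band re-entry equals
#' \code{targetAuc} (ratio x s). The rise contributes
#' \eqn{\Delta_{peak}(5\tau_r/(1-e^{-5}) - \tau_r)} and the decay
#' \eqn{\tau_d(\Delta_{peak} - k\sigma)}; the latter is solved for
#' \eqn{\tau_d}.
#'
#' @inheritParams calibrateDecay
#' @param targetAuc desired integral above baseline (ratio x s).
#' @return decay time constant (s).
#' @export
calibrateAucDecay <- function(amplitudePct, baselineMean = 1,
        noiseSd = 0.005, targetAuc, returnBandK = 2, riseTau = 2) {
    peakDelta <- amplitudePct * baselineMean / 100
    band <- returnBandK * noiseSd
    if (peakDelta <= band)
        stop(sprintf(
            "infeasible calibration: peak elevation %.4g not above the return band %.4g",
            peakDelta, band))
    r <- .RISE_MULT
    riseInt <- peakDelta * (r * riseTau / (1 - exp(-r)) - riseTau)
    if (targetAuc <= riseInt)
        stop(sprintf(
            "infeasible calibration: targetAuc %.4g below the rise-phase integral %.4g",
            targetAuc, riseInt))
    (targetAuc - riseInt) / (peakDelta - band)
}

#' Build a cohort configuration
#'
#' Lays the supplied per-stimulus presets end to end (one trace segment
#' per stimulus, each keeping its own epoch geometry within its segment)
#' and bundles them with responder fractions and heterogeneity settings.
#'
#' @param label cohort label.
#' @param presets named list of \linkS4class{TraceGenParams} (names are
#'   stimulus names) or of preset names understood by [tracePreset()].
#' @param responderFraction named numeric in [0,1]; stimuli missing from
#'   it default to 1.
#' @param nCells number of cells.
#' @param kclPositiveFraction probability that a cell is KCl-responsive.
#' @param amplitudeCv lognormal CV of per-cell amplitudes (0 = fixed).
#' @return a \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(label, presets, responderFraction = NULL,
        nCells = 100L, kclPositiveFraction = 0.3, amplitudeCv = 0.6) {
    if (is.character(presets)) {
        nm <- names(presets)
        presets <- lapply(presets, tracePreset)
        names(presets) <- if (is.null(nm))
            vapply(presets, function(p) p@epoch@stimulus, character(1))
            else nm
    }
    if (is.null(responderFraction)) responderFraction <- numeric()
    missing <- setdiff(names(presets), names(responderFraction))
    responderFraction[missing] <- 1
    new("CohortConfig", label = as.character(label),
        nCells = as.integer(nCells), presets = presets,
        responderFraction = responderFraction[names(presets)],
        kclPositiveFraction = kclPositiveFraction,
        amplitudeCv = amplitudeCv)
}

#' Simulate a cohort of taste cells
#'
#' Simulates \code{nCells} traces under a \linkS4class{CohortConfig}.
#' Each cell is one long trace containing one stimulus segment per
#' preset; per-cell responder labels are Bernoulli draws at the
#' configured fractions (the \code{"KCl"} stimulus uses
#' \code{kclPositiveFraction}), and responder amplitudes are drawn
#' lognormally around the preset mean with CV \code{amplitudeCv}. Every
#' cell uses a substream derived deterministically from the master seed
#' and the cell index, so cell \eqn{i} is identical whatever the cohort
#' size.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param seed master integer seed.
#' @return a \linkS4class{TasteTraceSet}; colData carries cohort label and
#'   per-stimulus ground truth (\code{true_responder_<stim>},
#'   \code{true_amplitude_pct_<stim>}).
#' @examples
#' cfg <- cohortConfig("ctl", list(SAC = tracePreset("ctl_SAC")),
#'     responderFraction = c(SAC = 0.5), nCells = 4)
#' simulateCohort(cfg, seed = 1)
#' @export
simulateCohort <- function(config, seed = 0L) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    presets <- config@presets
    stim <- names(presets)
    segLen <- vapply(presets, function(p)
        round(p@durationTotal / p@samplingInterval), numeric(1))
    dt <- presets[[1]]@samplingInterval
    if (any(vapply(presets, slot, numeric(1), "samplingInterval") != dt))
        stop("all presets in a cohort must share 'samplingInterval'")
    offsets <- c(0, cumsum(segLen))[seq_along(presets)] * dt
    nT <- sum(segLen)
    time <- (seq_len(nT) - 1L) * dt

    frac <- config@responderFraction
    if ("KCl" %in% stim) frac["KCl"] <- config@kclPositiveFraction
    sdlog <- sqrt(log(1 + config@amplitudeCv^2))

    ratio <- matrix(NA_real_, nrow = nT, ncol = config@nCells)
    truthResp <- matrix(FALSE, config@nCells, length(stim),
        dimnames = list(NULL, stim))
    truthAmp <- matrix(0, config@nCells, length(stim),
        dimnames = list(NULL, stim))
    for (i in seq_len(config@nCells)) {
        set.seed(.subSeed(seed, i))
        resp <- stats::runif(length(stim)) < frac[stim]
        amp <- vapply(seq_along(stim), function(j) {
            mu <- presets[[j]]@amplitudePct
            if (!resp[j] || mu <= 0) return(0)
            if (config@amplitudeCv == 0) return(mu)
            stats::rlnorm(1, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
        }, numeric(1))
        segs <- lapply(seq_along(stim), function(j) {
            p <- presets[[j]]
            p@responder <- resp[j]
            .simulateTraceVector(p, seed = NULL, amplitudePct = amp[j])
        })
        ratio[, i] <- unlist(segs, use.names = FALSE)
        truthResp[i, ] <- resp
        truthAmp[i, ] <- amp
    }
    ep <- S4Vectors::DataFrame(
        stimulus = stim,
        concentration_mM = vapply(presets, function(p)
            p@epoch@concentration, numeric(1)),
        start_s = offsets + vapply(presets, function(p) p@epoch@start,
            numeric(1)),
        end_s = offsets + vapply(presets, function(p) p@epoch@end,
            numeric(1)))
    cd <- S4Vectors::DataFrame(
        cell_id = sprintf("%s_cell%04d", config@label,
            seq_len(config@nCells)),
        group = config@label)
    for (s in stim) {
        cd[[paste0("true_responder_", s)]] <- truthResp[, s]
        cd[[paste0("true_amplitude_pct_", s)]] <- truthAmp[, s]
    }
    TasteTraceSet(ratio = ratio, time = time, epochs = ep, colData = cd)
}

#' Simulate two-bottle preference intake records
#'
#' Generates per animal x concentration x 24 h period intake records.
#' Each period's total intake is Normal(\code{dailyTotalMean},
#' \code{dailyTotalSd}) truncated at zero; the test bottle's share of the
#' total is a per-animal beta draw with mean \code{truePreference} and
#' precision \code{betaPrecision}, optionally shifted by a positional
#' \code{sideBias}; the test bottle's side alternates between periods, as
#' in a 48 h two-bottle test with a 24 h side swap.
#'
#' @param params an \linkS4class{IntakeGenParams}.
#' @param seed master integer seed.
#' @return a data.frame with columns \code{animal_id}, \code{group},
#'   \code{stimulus}, \code{concentration_mM}, \code{period},
#'   \code{test_intake}, \code{water_intake}, \code{test_side} and the
#'   ground-truth column \code{true_preference}.
#' @examples
#' rec <- simulatePreferenceRecords(
#'     IntakeGenParams(truePreference = 0.8, nAnimals = 3), seed = 1)
#' head(rec)
#' @export
simulatePreferenceRecords <- function(params, seed = 0L) {
    stopifnot(is(params, "IntakeGenParams"))
    validObject(params)
    conc <- params@concentrations
    p <- rep_len(params@truePreference, length(conc))
    out <- vector("list", params@nAnimals)
    for (i in seq_len(params@nAnimals)) {
        set.seed(.subSeed(seed, i))
        rows <- vector("list", length(conc))
        for (ci in seq_along(conc)) {
            share <- if (is.finite(params@betaPrecision) &&
                    p[ci] > 0 && p[ci] < 1)
                stats::rbeta(1, p[ci] * params@betaPrecision,
                    (1 - p[ci]) * params@betaPrecision)
            else p[ci]
            per <- seq_len(params@nPeriods)
            total <- pmax(stats::rnorm(length(per), params@dailyTotalMean,
                params@dailyTotalSd), 0)
            side <- ifelse((i + per) %% 2 == 0, "left", "right")
            eff <- pmin(pmax(share +
                ifelse(side == "left", params@sideBias,
                    -params@sideBias), 0), 1)
            rows[[ci]] <- data.frame(
                animal_id = sprintf("%s_a%02d", params@group, i),
                group = params@group, stimulus = params@stimulus,
                concentration_mM = conc[ci], period = per,
                test_intake = total * eff,
                water_intake = total * (1 - eff),
                test_side = side, true_preference = p[ci],
                stringsAsFactors = FALSE)
        }
        out[[i]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
}
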