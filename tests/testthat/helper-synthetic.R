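# Shared fixtures, built in code.

# baseline stats object without estimation, for constructed traces
fixedBaseline <- function(mean, sd) {
    structure(list(mean = mean, sd = sd, window = c(NA, NA), n = NA),
        class = "BaselineStats")
}

# noise-free trace on a 1 s grid with a square pulse of `height` above
# `base` spanning sample times [from, to] inclusive
squarePulseTrace <- function(n = 60, base = 1, height = 0.5, from = 20,
        to = 29) {
    tm <- seq_len(n) - 1
    y <- rep(base, n)
    y[tm >= from & tm <= to] <- base + height
    list(time = tm, ratio = y)
}

# quantify a whole preset-based cohort and return the calls data.frame
quantifyPresetCohort <- function(preset, nCells, seed,
        responderFraction = 1, amplitudeCv = 0.6,
        params = detectionParams()) {
    p <- tracePreset(preset)
    stim <- p@epoch@stimulus
    cfg <- cohortConfig("g", stats::setNames(list(p), stim),
        responderFraction = stats::setNames(responderFraction, stim),
        nCells = nCells, amplitudeCv = amplitudeCv)
    as.data.frame(quantifyCells(simulateCohort(cfg, seed = seed), params))
}

# independent Pearson chi-square oracle: expected counts from marginals
chisqOracle <- function(tab) {
    tot <- sum(tab)
    exp <- outer(rowSums(tab), colSums(tab)) / tot
    sum((tab - exp)^2 / exp)
}
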