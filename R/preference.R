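# Two-bottle preference analysis: 48 h preference ratios with a 24 h
# side swap, repeated-measures two-way ANOVA over concentration series,
# and per-concentration Student's t-tests.

.checkIntakeSchema <- function(records) {
    need <- c("animal_id", "group", "stimulus", "concentration_mM",
        "period", "test_intake", "water_intake")
    missing <- setdiff(need, colnames(records))
    if (length(missing))
        stop("intake records lack column(s): ",
            paste(missing, collapse = ", "))
    if (!nrow(records))
        stop("intake table is empty")
    if (any(records$test_intake < 0) || any(records$water_intake < 0))
        stop("intake volumes must be >= 0")
    invisible(records)
}

#' 48 h preference ratio
#'
#' Pools the intake volumes of one animal at one concentration over all
#' its 24 h periods and returns
#' \code{sum(test) / sum(test + water)}. Pooling volumes (rather than
#' averaging daily ratios) makes the two periods' side swap cancel any
#' positional drinking bias.
#'
#' @param records intake rows for a single animal x stimulus x
#'   concentration (one row per period).
#' @param nPeriods number of periods that must be present.
#' @return the preference ratio in [0, 1].
#' @examples
#' rec <- data.frame(animal_id = "a1", group = "ctl", stimulus = "SAC",
#'     concentration_mM = 2, period = 1:2, test_intake = c(8, 2),
#'     water_intake = c(2, 8))
#' preferenceRatio(rec)  # side-swap cancellation: 10/20 = 0.5
#' @export
preferenceRatio <- function(records, nPeriods = 2L) {
    .checkIntakeSchema(records)
    key <- unique(records[, c("animal_id", "stimulus",
        "concentration_mM")])
    if (nrow(key) != 1L)
        stop("records must belong to a single animal x stimulus x concentration")
    missing <- setdiff(seq_len(nPeriods), records$period)
    if (length(missing))
        stop(sprintf("missing 24 h period(s): %s",
            paste(missing, collapse = ", ")))
    total <- sum(records$test_intake) + sum(records$water_intake)
    if (total <= 0)
        stop("zero total intake: preference ratio undefined")
    sum(records$test_intake) / total
}

#' Per-animal preference-ratio table
#'
#' Computes the pooled 48 h [preferenceRatio()] for every animal x
#' stimulus x concentration cell of an intake table.
#'
#' @param records an intake table (see [simulatePreferenceRecords()] for
#'   the schema).
#' @param nPeriods periods required per cell.
#' @return a data.frame with one row per animal x stimulus x
#'   concentration: \code{animal_id}, \code{group}, \code{stimulus},
#'   \code{concentration_mM}, \code{ratio}.
#' @export
preferenceTable <- function(records, nPeriods = 2L) {
    .checkIntakeSchema(records)
    key <- interaction(records$animal_id, records$stimulus,
        records$concentration_mM, drop = TRUE)
    out <- do.call(rbind, lapply(split(records, key), function(r) {
        data.frame(animal_id = r$animal_id[1], group = r$group[1],
            stimulus = r$stimulus[1],
            concentration_mM = r$concentration_mM[1],
            ratio = preferenceRatio(r, nPeriods = nPeriods),
            stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out[order(out$stimulus, out$group, out$animal_id,
        out$concentration_mM), , drop = FALSE]
}

.checkCompleteSeries <- function(pref) {
    conc <- sort(unique(pref$concentration_mM))
    tab <- table(pref$animal_id, pref$concentration_mM)
    bad <- which(tab != 1L, arr.ind = TRUE)
    if (nrow(bad))
        stop("incomplete concentration series; missing/duplicated cells: ",
            paste(sprintf("%s @ %s mM", rownames(tab)[bad[, 1]],
                colnames(tab)[bad[, 2]]), collapse = ", "))
    conc
}

#' Repeated-measures two-way ANOVA on preference ratios
#'
#' Diet group is the between-subject factor and concentration the
#' within-subject (repeated) factor; the model is the univariate
#' within-subject ANOVA \code{ratio ~ group * concentration +
#' Error(animal / concentration)}. Bonferroni post-hoc contrasts compare
#' the groups at each concentration (raw t-test p-values multiplied by
#' the number of concentrations). A Greenhouse-Geisser sphericity
#' correction of the within-subject p-values is available via
#' \code{ggCorrection = TRUE} (requires the \pkg{car} package).
#'
#' @param pref a [preferenceTable()] for a single stimulus.
#' @param ggCorrection apply the Greenhouse-Geisser correction.
#' @param welch use Welch t-tests for the contrasts.
#' @return a list with \code{effects} (data.frame: effect, df1, df2, F,
#'   p) and \code{contrasts} (per-concentration Bonferroni-adjusted
#'   comparisons).
#' @examples
#' rec <- rbind(
#'     simulatePreferenceRecords(IntakeGenParams(0.8, nAnimals = 5,
#'         group = "ctl"), seed = 1),
#'     simulatePreferenceRecords(IntakeGenParams(0.5, nAnimals = 5,
#'         group = "ob"), seed = 2))
#' rmTwoWayAnova(preferenceTable(rec))$effects
#' @export
rmTwoWayAnova <- function(pref, ggCorrection = FALSE, welch = FALSE) {
    if (length(unique(pref$stimulus)) != 1L)
        stop("supply a preference table for a single stimulus")
    if (length(unique(pref$group)) < 2L)
        stop("need at least 2 groups")
    nPer <- table(unique(pref[, c("animal_id", "group")])$group)
    if (any(nPer < 2))
        stop("need at least 2 animals per group")
    conc <- .checkCompleteSeries(pref)
    d <- data.frame(ratio = pref$ratio,
        group = factor(pref$group),
        conc = factor(pref$concentration_mM, levels = conc),
        animal = factor(pref$animal_id))
    fit <- stats::aov(ratio ~ group * conc + Error(animal / conc),
        data = d)
    s <- summary(fit)
    betw <- s[["Error: animal"]][[1]]
    with <- s[["Error: animal:conc"]][[1]]
    rn <- function(tab) trimws(rownames(tab))
    pick <- function(tab, term) {
        i <- match(term, rn(tab))
        res <- match("Residuals", rn(tab))
        data.frame(effect = term, df1 = tab$Df[i], df2 = tab$Df[res],
            F = tab[["F value"]][i], p = tab[["Pr(>F)"]][i],
            stringsAsFactors = FALSE)
    }
    effects <- rbind(pick(betw, "group"), pick(with, "conc"),
        pick(with, "group:conc"))
    if (ggCorrection) {
        if (!requireNamespace("car", quietly = TRUE))
            stop("ggCorrection = TRUE requires the 'car' package")
        wide <- stats::reshape(
            pref[, c("animal_id", "group", "concentration_mM", "ratio")],
            idvar = c("animal_id", "group"),
            timevar = "concentration_mM", direction = "wide")
        ymat <- as.matrix(wide[, -(1:2), drop = FALSE])
        mlm <- stats::lm(ymat ~ group, data = wide)
        idata <- data.frame(conc = factor(conc, levels = conc))
        aa <- summary(car::Anova(mlm, idata = idata, idesign = ~conc,
            type = "III"), multivariate = FALSE)
        gg <- aa$pval.adjustments
        for (term in c("conc", "group:conc")) {
            ri <- match(term, rownames(gg))
            if (!is.na(ri))
                effects$p[effects$effect == term] <-
                    gg[ri, "Pr(>F[GG])"]
        }
        attr(effects, "gg_epsilon") <- gg[, "GG eps"]
    }
    effects$stars <- significanceStars(effects$p)
    nConc <- length(conc)
    contrasts <- do.call(rbind, lapply(conc, function(cc) {
        sub <- pref[pref$concentration_mM == cc, ]
        gs <- split(sub$ratio, sub$group)
        pairs <- utils::combn(names(gs), 2)
        do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
            tt <- twoSampleT(gs[[pairs[1, k]]], gs[[pairs[2, k]]],
                welch = welch)
            data.frame(concentration_mM = cc, group1 = pairs[1, k],
                group2 = pairs[2, k], t = tt$statistic,
                p.raw = tt$p.value,
                p.adj = min(1, tt$p.value * nConc),
                stringsAsFactors = FALSE)
        }))
    }))
    contrasts$stars <- significanceStars(contrasts$p.adj)
    list(effects = effects, contrasts = contrasts)
}

#' Per-concentration Student's t-tests
#'
#' Unadjusted two-sample t-tests between two groups at each
#' concentration of a preference series (the per-concentration tier of
#' the two-tier analysis; Bonferroni adjustment applies only to the
#' ANOVA post-hoc contrasts).
#'
#' @param pref a [preferenceTable()] for a single stimulus and two
#'   groups.
#' @param welch use Welch t-tests.
#' @return a data.frame: \code{concentration_mM}, \code{t}, \code{p},
#'   \code{stars}.
#' @export
perConcentrationTests <- function(pref, welch = FALSE) {
    if (length(unique(pref$stimulus)) != 1L)
        stop("supply a preference table for a single stimulus")
    grp <- unique(pref$group)
    if (length(grp) != 2L)
        stop("per-concentration t-tests need exactly 2 groups")
    out <- do.call(rbind, lapply(sort(unique(pref$concentration_mM)),
        function(cc) {
            sub <- pref[pref$concentration_mM == cc, ]
            tt <- twoSampleT(sub$ratio[sub$group == grp[1]],
                sub$ratio[sub$group == grp[2]], welch = welch)
            data.frame(concentration_mM = cc, t = tt$statistic,
                p = tt$p.value)
        }))
    out$stars <- significanceStars(out$p)
    out
}

#' Dose-curve summary of preference ratios
#'
#' Mean, SD and n of the preference ratio per group x concentration
#' (the plotting convention for concentration series: mean with
#' standard deviation).
#'
#' @param pref a [preferenceTable()].
#' @return a data.frame: \code{stimulus}, \code{group},
#'   \code{concentration_mM}, \code{mean_ratio}, \code{sd_ratio},
#'   \code{n}.
#' @export
doseCurveSummary <- function(pref) {
    key <- interaction(pref$stimulus, pref$group, pref$concentration_mM,
        drop = TRUE)
    out <- do.call(rbind, lapply(split(pref, key), function(r) {
        data.frame(stimulus = r$stimulus[1], group = r$group[1],
            concentration_mM = r$concentration_mM[1],
            mean_ratio = mean(r$ratio), sd_ratio = stats::sd(r$ratio),
            n = nrow(r), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out[order(out$stimulus, out$group, out$concentration_mM), ,
        drop = FALSE]
}
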