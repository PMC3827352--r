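# End-to-end orchestration: simulate -> quantify -> type -> compare, and
# simulate-intake -> preference statistics. Configured by YAML (or an
# equivalent nested list); every run writes a manifest with the config
# hash and master seed so outputs are traceable and reruns are
# reproducible.

.readRunConfig <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop(sprintf("config file '%s' not found", config))
        config <- yaml::read_yaml(config)
    }
    if (!is.list(config)) stop("config must be a list or a YAML path")
    config
}

.configMd5 <- function(config) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(config, tmp)
    unname(tools::md5sum(tmp))
}

.detectionFromConfig <- function(config) {
    d <- config$detection
    if (is.null(d)) return(detectionParams())
    do.call(detectionParams, stats::setNames(d, c(
        baseline_window = "baselineWindow", min_run = "minRun",
        threshold_k = "thresholdK", return_band_k = "returnBandK",
        return_run = "returnRun", post_window = "postWindow",
        sd_floor = "sdFloor", smooth_peak = "smoothPeak",
        no_return_policy = "noReturnPolicy")[names(d)]))
}

.writeOutputs <- function(outDir, writer) {
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    written <- character()
    note <- function(path) written <<- c(written, path)
    tryCatch(writer(note), error = function(e) {
        unlink(written)   # no partial result bundles
        stop(e)
    })
}

.writeManifest <- function(path, config, seed, extra = list()) {
    manifest <- c(list(
        config_md5 = .configMd5(config),
        seed = as.integer(seed),
        package = "TasteCa",
        package_version = as.character(utils::packageVersion("TasteCa")),
        r_version = R.version.string), extra)
    yaml::write_yaml(manifest, path)
}

#' Run the calcium-imaging analysis pipeline
#'
#' Simulates the configured cohorts, quantifies every trace, infers cell
#' types from KCl responsiveness, gates the umami (MPG) analysis on
#' KCl-negative cells, tabulates responder frequencies with chi-square
#' comparisons of each cohort against the reference cohort, and runs
#' one-way ANOVAs with Bonferroni post-hoc comparisons for amplitude,
#' AUC and duration per stimulus. Responses that never returned to
#' baseline are kept in frequency and amplitude summaries but excluded
#' from AUC and duration (or from everything, under the
#' \code{"all"} no-return policy of [detectionParams()]).
#'
#' The config (YAML file or list) needs \code{seed}, \code{n_cells}, and
#' a \code{groups} map whose entries give \code{presets} (stimulus name
#' to [tracePreset()] name), \code{responder_fraction} and
#' \code{kcl_positive_fraction}; optional keys: \code{amplitude_cv},
#' \code{detection} (see [detectionParams()], snake_case keys),
#' \code{reference_group}. See
#' \code{system.file("extdata", "demo-imaging.yaml", package =
#' "TasteCa")}.
#'
#' @param config YAML path or config list.
#' @param outDir output directory; created if needed.
#' @return invisibly, a list with the response calls, profiles, tables
#'   and test results (all also written as CSV, plus
#'   \code{manifest.yaml}).
#' @export
runImagingPipeline <- function(config, outDir) {
    config <- .readRunConfig(config)
    if (is.null(config$groups) || !length(config$groups))
        stop("config needs a non-empty 'groups' section")
    seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
    nCells <- if (is.null(config$n_cells)) 50L else
        as.integer(config$n_cells)
    ampCv <- if (is.null(config$amplitude_cv)) 0.6 else
        config$amplitude_cv
    params <- .detectionFromConfig(config)
    refGroup <- if (is.null(config$reference_group))
        names(config$groups)[1] else config$reference_group

    callsList <- list()
    for (gi in seq_along(config$groups)) {
        g <- config$groups[[gi]]
        label <- names(config$groups)[gi]
        presetNames <- unlist(g$presets)
        cfg <- cohortConfig(label,
            presets = stats::setNames(as.character(presetNames),
                names(presetNames)),
            responderFraction = unlist(g$responder_fraction),
            nCells = nCells,
            kclPositiveFraction = if (is.null(g$kcl_positive_fraction))
                0.3 else g$kcl_positive_fraction,
            amplitudeCv = ampCv)
        cohort <- simulateCohort(cfg, seed = seed + 1000L * gi)
        callsList[[label]] <- quantifyCells(cohort, params)
    }
    calls <- do.call(rbind, lapply(callsList, as.data.frame))
    rownames(calls) <- NULL
    profiles <- cellProfiles(calls)
    umami <- suppressMessages(suppressWarnings(
        selectUmamiResponses(calls, profiles)))

    dropNoReturn <- params$noReturnPolicy == "all"
    stimuli <- setdiff(unique(calls$stimulus), "KCl")
    groups <- names(config$groups)
    freqRows <- list(); compRows <- list(); tableRows <- list()
    for (s in stimuli) {
        sCalls <- if (s == "MPG") {
            mpgIds <- umami$cell_id
            rbind(umami,
                calls[calls$stimulus != "MPG" &
                    calls$cell_id %in% mpgIds, ])
        } else calls
        if (dropNoReturn)
            sCalls <- sCalls[!(sCalls$stimulus == s &
                sCalls$excluded_no_return), , drop = FALSE]
        tab <- buildResponderTable(sCalls, s, cohorts = intersect(
            groups, unique(sCalls$group[sCalls$stimulus == s])))
        tableRows[[s]] <- data.frame(stimulus = s,
            group = rownames(tab), responsive = tab[, 1],
            non_responsive = tab[, 2], row.names = NULL)
        for (g in setdiff(rownames(tab), refGroup)) {
            sub <- tab[c(refGroup, g), , drop = FALSE]
            cs <- chiSquareIndependence(sub)
            freqRows[[paste(s, g)]] <- data.frame(stimulus = s,
                group1 = refGroup, group2 = g,
                statistic = cs$statistic, df = cs$df, p = cs$p.value,
                stars = significanceStars(cs$p.value))
        }
        resp <- sCalls[sCalls$stimulus == s & sCalls$responsive, ]
        for (m in c("amplitude_pct", "auc", "duration_s")) {
            vals <- resp[[m]]
            ok <- !is.na(vals)
            if (length(unique(resp$group[ok])) < 2L ||
                any(table(resp$group[ok]) < 2L)) next
            gc <- oneWayAnovaBonferroni(vals[ok], resp$group[ok],
                measure = m, stimulus = s)
            compRows[[paste(s, m)]] <- cbind(
                data.frame(stimulus = s, measure = m, F = gc$F,
                    df1 = gc$df[1], df2 = gc$df[2],
                    p.anova = gc$p.value),
                gc$pairwise)
        }
    }
    result <- list(calls = calls, profiles = as.data.frame(profiles),
        responder_tables = do.call(rbind, tableRows),
        frequency_tests = do.call(rbind, freqRows),
        comparisons = do.call(rbind, compRows))
    .writeOutputs(outDir, function(note) {
        w <- function(obj, name) {
            path <- file.path(outDir, name)
            note(path)
            utils::write.csv(obj, path, row.names = FALSE)
        }
        w(result$calls, "response_calls.csv")
        w(result$profiles, "cell_profiles.csv")
        w(result$responder_tables, "responder_tables.csv")
        w(result$frequency_tests, "frequency_tests.csv")
        w(result$comparisons, "comparisons.csv")
        mf <- file.path(outDir, "manifest.yaml")
        note(mf)
        .writeManifest(mf, config, seed,
            list(n_cells = nCells, groups = names(config$groups)))
    })
    invisible(result)
}

#' Run the two-bottle preference pipeline
#'
#' Either simulates intake records for every configured stimulus and
#' group (config key \code{stimuli}: per-stimulus \code{concentrations}
#' and per-group \code{true_preference} vectors) or reads an existing
#' intake CSV (config key \code{intake_file}), then computes pooled
#' 48 h preference ratios, the repeated-measures two-way ANOVA with
#' Bonferroni post-hoc contrasts, unadjusted per-concentration t-tests,
#' and the mean +/- SD dose-curve summary. See
#' \code{system.file("extdata", "demo-preference.yaml", package =
#' "TasteCa")}.
#'
#' @param config YAML path or config list.
#' @param outDir output directory.
#' @return invisibly, a list with the intake records, ratio table and
#'   statistics (also written as CSV plus \code{manifest.yaml}).
#' @export
runPreferencePipeline <- function(config, outDir) {
    config <- .readRunConfig(config)
    seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
    if (!is.null(config$intake_file)) {
        records <- readIntake(config$intake_file)
    } else {
        if (is.null(config$stimuli) || !length(config$stimuli))
            stop("config needs 'stimuli' (or 'intake_file')")
        nAnimals <- if (is.null(config$n_animals)) 5L else
            as.integer(config$n_animals)
        records <- list()
        si <- 0L
        for (s in names(config$stimuli)) {
            spec <- config$stimuli[[s]]
            for (g in names(spec$true_preference)) {
                si <- si + 1L
                params <- IntakeGenParams(
                    truePreference = unlist(spec$true_preference[[g]]),
                    dailyTotalMean = if (is.null(config$daily_total_mean))
                        6 else config$daily_total_mean,
                    dailyTotalSd = if (is.null(config$daily_total_sd))
                        1 else config$daily_total_sd,
                    nAnimals = nAnimals,
                    concentrations = unlist(spec$concentrations),
                    betaPrecision = if (is.null(config$beta_precision))
                        50 else config$beta_precision,
                    stimulus = s, group = g)
                records[[paste(s, g)]] <-
                    simulatePreferenceRecords(params,
                        seed = seed + 1000L * si)
            }
        }
        records <- do.call(rbind, records)
        rownames(records) <- NULL
    }
    pref <- preferenceTable(records)
    anovaRows <- list(); contrastRows <- list(); tRows <- list()
    for (s in unique(pref$stimulus)) {
        sub <- pref[pref$stimulus == s, ]
        rma <- rmTwoWayAnova(sub,
            ggCorrection = isTRUE(config$gg_correction),
            welch = isTRUE(config$welch))
        anovaRows[[s]] <- cbind(stimulus = s, rma$effects)
        contrastRows[[s]] <- cbind(stimulus = s, rma$contrasts)
        if (length(unique(sub$group)) == 2L)
            tRows[[s]] <- cbind(stimulus = s,
                perConcentrationTests(sub,
                    welch = isTRUE(config$welch)))
    }
    result <- list(records = records, ratios = pref,
        anova = do.call(rbind, anovaRows),
        contrasts = do.call(rbind, contrastRows),
        t_tests = do.call(rbind, tRows),
        dose_summary = doseCurveSummary(pref))
    .writeOutputs(outDir, function(note) {
        w <- function(obj, name) {
            path <- file.path(outDir, name)
            note(path)
            utils::write.csv(obj, path, row.names = FALSE)
        }
        w(result$records, "intake_records.csv")
        w(result$ratios, "preference_ratios.csv")
        w(result$anova, "rm_anova.csv")
        w(result$contrasts, "posthoc_contrasts.csv")
        if (!is.null(result$t_tests)) w(result$t_tests, "t_tests.csv")
        w(result$dose_summary, "dose_summary.csv")
        mf <- file.path(outDir, "manifest.yaml")
        note(mf)
        .writeManifest(mf, config, seed)
    })
    invisible(result)
}
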