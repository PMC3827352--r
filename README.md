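# TasteCa

Quantification of taste-evoked calcium responses in peripheral taste
receptor cells, and analysis of two-bottle preference tests.

Isolated taste receptor cells loaded with fura-2 report cytosolic
calcium as the F340/F380 excitation ratio. When a taste stimulus
(saccharin, acesulfame K, monopotassium glutamate, denatonium) or a
50 mM KCl depolarisation control is bath-applied, responsive cells show
a calcium transient. TasteCa implements the standard analysis of such
recordings:

- **Detection** — a response is called when the ratio rises more than
  2 baseline SDs above the pre-stimulus baseline (with a 3-sample run
  requirement so single noise spikes do not fire the rule);
- **Amplitude** — `100 × (peak − baseline) / baseline`, the percent
  increase over baseline;
- **AUC** — the trapezoidal integral of the supra-baseline ratio from
  response onset to the return to baseline, a proportional measure of
  mobilised calcium;
- **Duration** — onset to return-to-baseline; responses that never
  return are excluded from AUC/duration summaries;
- **Cell typing** — KCl-responsive cells are presumptive Type III
  (voltage-gated calcium channels); umami (MPG) analysis is restricted
  to KCl-negative cells so potassium-driven depolarisation is not
  mistaken for umami transduction;
- **Cohort statistics** — chi-square tests on responder frequencies,
  one-way ANOVAs with Bonferroni post-hoc comparisons on response
  properties, Student's t-tests (significance at p < 0.05);
- **Two-bottle preference** — 48 h preference ratios
  (test intake / total intake, pooled across the 24 h side swap),
  repeated-measures two-way ANOVA over ascending concentration series
  with Bonferroni contrasts and per-concentration t-tests.

A seeded synthetic-data generator produces fura-2-like traces (baseline
noise plus exponential-rise/exponential-decay transients) and intake
records with known ground truth; packaged presets pin amplitudes,
durations and areas to published cohort means so the whole pipeline can
be validated by parameter recovery.

## Worked example

Simulate a 50-cell control cohort (saccharin plus the KCl control),
quantify every trace, and type the cells:

```r
library(TasteCa)

cfg <- cohortConfig("ctl",
    list(SAC = tracePreset("ctl_SAC"), KCl = tracePreset("kcl")),
    responderFraction = c(SAC = 0.4), nCells = 50,
    kclPositiveFraction = 0.3)
cohort <- simulateCohort(cfg, seed = 42)
cohort
#> TasteTraceSet: 50 cells, 480 frames (0-479 s, dt 1 s)
#>   assays: ratio
#>   epochs: SAC 2 mM @60-90 s; KCl 50 mM @300-330 s
#>   colData: cell_id, group, true_responder_SAC, true_amplitude_pct_SAC, ...

calls <- quantifyCells(cohort)
sac <- as.data.frame(calls[calls$stimulus == "SAC", ])
sum(sac$responsive)                          # 21 of 50 cells responded
mean(sac$amplitude_pct[sac$responsive])      # 75.3 (% over baseline)
mean(sac$duration_s, na.rm = TRUE)           # 52.3 s

table(cellProfiles(calls)$inferred_type)
#>  presumptive_TypeII presumptive_TypeIII
#>                  35                  15

buildResponderTable(sac, "SAC")
#>     responsive non_responsive
#> ctl         21             29
```

With the `ctl_SAC` preset the true responder fraction is 0.40 and the
true mean amplitude 74.2% over baseline: the 50-cell cohort recovers
21/50 responders and a mean measured amplitude of 75.3%, and the
KCl-positive fraction (0.30) yields 15 presumptive Type III cells.
Contingency tables from several cohorts feed
`chiSquareIndependence()`, and amplitudes/AUCs/durations feed
`oneWayAnovaBonferroni()`.

End-to-end runs, including the two-bottle preference analysis, are
driven by YAML configurations:

```r
runImagingPipeline(system.file("extdata", "demo-imaging.yaml",
    package = "TasteCa"), "imaging-out")
runPreferencePipeline(system.file("extdata", "demo-preference.yaml",
    package = "TasteCa"), "preference-out")
```

Each run writes tidy CSVs (response calls, cell profiles, responder
tables, test results, preference ratios, dose curves) and a
`manifest.yaml` recording the configuration hash and master seed;
reruns with the same configuration are bit-identical.

## Documentation

The methods vignette (`vignettes/taste-calcium-analysis.Rmd`) describes
the detection and quantification model, every tunable parameter with
its default and rationale, what the synthetic generator does and does
not emulate, and known numerical behaviour (peak-reading bias, offset
delay of run-based return criteria).
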