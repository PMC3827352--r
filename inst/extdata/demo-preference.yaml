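# Demo configuration for runPreferencePipeline(): five stimuli at their
# four-step ascending concentration series (mM), two diet groups with
# five animals each, 48 h per concentration with a 24 h side swap.
# True preferences are illustrative dose curves (appetitive stimuli
# rise with concentration, the bitter stimulus falls).
seed: 1
n_animals: 5
daily_total_mean: 6
daily_total_sd: 1
beta_precision: 50
stimuli:
  AceK:
    concentrations: [1, 2, 20, 50]
    true_preference:
      ctl: [0.55, 0.60, 0.80, 0.90]
      ob:  [0.55, 0.58, 0.70, 0.72]
  sucrose:
    concentrations: [5, 50, 150, 300]
    true_preference:
      ctl: [0.55, 0.70, 0.85, 0.95]
      ob:  [0.55, 0.68, 0.82, 0.75]
  saccharin:
    concentrations: [1, 2, 10, 20]
    true_preference:
      ctl: [0.65, 0.75, 0.85, 0.85]
      ob:  [0.50, 0.55, 0.80, 0.85]
  MPG:
    concentrations: [10, 30, 100, 300]
    true_preference:
      ctl: [0.50, 0.50, 0.55, 0.65]
      ob:  [0.50, 0.50, 0.52, 0.55]
  Den:
    concentrations: [0.1, 0.5, 1, 10]
    true_preference:
      ctl: [0.45, 0.35, 0.20, 0.05]
      ob:  [0.45, 0.38, 0.25, 0.15]
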