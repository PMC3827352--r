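# Demo configuration for runImagingPipeline(): three cohorts
# (control, obese male, obese female), four tastants plus the 50 mM KCl
# depolarisation control. Responder fractions are illustrative defaults;
# amplitude means come from the packaged presets.
seed: 1
n_cells: 40
amplitude_cv: 0.6
reference_group: ctl
detection:
  baseline_window: 30
  min_run: 3
  return_band_k: 2
  return_run: 5
  post_window: 60
groups:
  ctl:
    presets: {SAC: ctl_SAC, AceK: ctl_ACEK, MPG: ctl_MPG, Den: ctl_DEN, KCl: kcl}
    responder_fraction: {SAC: 0.40, AceK: 0.35, MPG: 0.25, Den: 0.25}
    kcl_positive_fraction: 0.30
  obM:
    presets: {SAC: obM_SAC, AceK: obM_ACEK, MPG: obM_MPG, Den: obM_DEN, KCl: kcl}
    responder_fraction: {SAC: 0.20, AceK: 0.18, MPG: 0.25, Den: 0.25}
    kcl_positive_fraction: 0.30
  obF:
    presets: {SAC: obF_SAC, AceK: obF_ACEK, MPG: obF_MPG, Den: obF_DEN, KCl: kcl}
    responder_fraction: {SAC: 0.08, AceK: 0.15, MPG: 0.25, Den: 0.25}
    kcl_positive_fraction: 0.30
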