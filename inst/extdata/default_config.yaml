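# Default pipeline configuration: cohort sizes follow the documented study
# design (10 traces per electrophysiology arm, 3 plates per assay arm, 15
# images per imaging arm); thresholds are the package defaults.
seed: 1
output_dir: results
cohorts:
  traces: 10
  plates: 3
  images: 15
thresholds:
  depth_criterion: 5      # mV below baseline for episode detection
  min_duration: 0.5       # s of sustained excursion
  max_gap: 0.3            # s of bridged above-criterion gaps
  alpha: 0.05             # letter-display significance level
  blur_sigma: 2           # px, segmentation smoothing
  threshold_frac: 0.5     # fraction of foreground dynamic range
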