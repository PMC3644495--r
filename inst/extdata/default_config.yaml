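# Default pipeline configuration. Every constant here is the standard
# printed value of the analysis protocol; override per run with a copy of
# this file.
io:
  artifact_max_positive_uv: 50      # drop positive-going spikes <= this (uV)
  inclusion_threshold_hz: 0.25      # strict early burst-incidence gate
  inclusion_window_s: 300           # gate window (first 5 minutes)
  stability_bin_s: 300              # array-rate stability bin (5 minutes)
  div_immature: [14, 25]            # days in vitro, inclusive
  div_mature: [37, 61]
burst:
  min_spikes_per_channel: 4
  channel_window_s: 0.100
  min_channels: 4
  overlap_window_s: 0.250
measures:
  bin_width_s: 0.004                # network spike rate bin (4 ms)
  profile_window_s: [0.1, 0.3]      # pre/post t0 extent of the profile
  active_channel_rule: burst
stats:
  family_size: 4                    # family-wise alpha = 0.05 / family_size
  direction_alpha: 0.05             # marker-level threshold for directions
  anova_alpha: 0.05
simulate:
  preset: mature_control
  n_cultures: 6
  duration_s: 600
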