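# Example pipeline configuration. Every key is optional; omitted keys use
# the package defaults. Sections map onto rule_config(), eval_config() and
# sim_config().
rule:
  plt_min: 80000            # platelet alarm threshold, count/mm3 (strict <)
  plt_max_plausible: 1000000
  inr_max: 2.0              # INR alarm threshold (strict >)
  inr_min_plausible: 0.5
  decline_fraction: 0.5     # relative platelet decline for chronic patients
  chronic_hemonc_codes: [C81, C82, C83, C84, C85, C86, C87, C88, C89, C90,
                         C91, C92, C93, C94, C95, C96]
  inr_exclusion_codes: [D66, D67, D68]
  prefix_match: true
  ecmo_pre_hours: 2
  ecmo_post_hours: 12
eval:
  tolerance_hours: 4        # snap window around reference onsets/ends
  merge_gap_hours: 24       # strict "less than" merge of nearby episodes
  apply_merge_to: both      # or reference_only
sim:
  n_patients: 168
  seed: 1
  episode_prevalence: 0.21
  chronic_prevalence: 0.1
  inr_exclusion_prevalence: 0.05
  ecmo_prevalence: 0.05
  noise_cv: 0.05
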