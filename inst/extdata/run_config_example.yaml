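# Example run configuration for the faersignal pipeline.
# Exactly one of `input_paths:` (FAERS-style '$'-delimited quarterly files)
# or `synthetic:` (arguments to synthetic_config()) may be present.

target: VONOPRAZAN          # focal drug; token match captures salt forms
seed: 1                     # single run seed; all randomness flows from it
output_dir: faersignal_out

synthetic:
  n_reports: 20000          # unique reports in the simulated database
  focal_drug_share: 0.10    # fraction with the focal drug as primary suspect
  onset_shape_beta: 0.49    # Weibull shape (<1 = early-failure hazard)
  onset_scale_alpha: 19.73  # Weibull scale, days
  duplicate_rate: 0.03      # injected follow-up duplicates (earlier FDA_DT)
  partial_date_rate: 0.05   # start dates truncated to YYYYMM

# Positivity thresholds (defaults shown); uncomment to override.
# thresholds:
#   ror_min: 3
#   prr_min: 2
#   chi2_min: 4
#   ebgm05_min: 2

fdr_method: BH              # or bonferroni
ic_mode: closed_form        # or ic_from_ebgm
severity_correct: true      # Yates continuity correction
onset_offset: auto          # +0.5 d for fitting only when day-0 events exist
onset_ci: wald              # or bootstrap
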