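# Default pipeline configuration: 61-patient synthetic cohort at desk scale
# (cell counts 1/100 of full sections). Omitted values fall back to the
# package defaults documented in ?cohort_config.
cohort:
  n_patients: 61
  count_multiplier: 0.01
  seed: 20260924
  survival_model:
    os_median: 43.33
    pfs_median: 19.8
    log_hr_os: 1.156881   # log(3.18)
    log_hr_pfs: 1.040277  # log(2.83)
    high_fraction: 0.5
    censor_time: 120
    censor_fraction: 0.33
robustness:
  fractions: [0.70, 0.75, 0.80, 0.85, 0.90, 0.95, 1.00]
  n_reps: 1000
  alpha: 0.05
survival:
  force: [stromal_group, lym_group]
validation:
  simulate: true
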