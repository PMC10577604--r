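# Demo configuration for `folliscape run --config demo_cohort.yaml`:
# a 20-patient synthetic cohort with inter-follicular co-localization of
# CD8+FOXP3+ with CD4+CD8+ cells linked to relapse hazard.
n_patients: 20
tiles_per_patient: 2
hazard_spec:
  coupling: -1.5
baseline_hazard: 0.15
censor_horizon: 12
seed: 1
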