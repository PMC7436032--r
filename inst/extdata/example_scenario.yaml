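# Example cohort scenario for `armswing`: a small smoke-test study.
# Omitted keys fall back to the reference scenario defaults.
n_control: 4
n_patient: 4
trials_per_subject: 3
duration_s: 10
sample_rate_hz: 50
seed: 7
control_left:
  swingAmplitude: 6.1
  anteriorFraction: 0.30
control_right:
  swingAmplitude: 7.0
  anteriorFraction: 0.30
patient_las:
  swingAmplitude: 4.85
  anteriorFraction: 0.44
  tremorHz: 6
  tremorAmplitude: 54
patient_mas:
  swingAmplitude: 3.6
  anteriorFraction: 0.44
  tremorHz: 6
  tremorAmplitude: 118
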