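# Demonstration pipeline configuration: a simulated obese cohort at the
# development-sample scale, classified with the union rule.
simulation:
  n_subjects: 398
  mode: direct_status
  population: obese
rule: union
hwe_alpha: 0.05
hwe_action: exclude
alpha: 0.05
seed: 42
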