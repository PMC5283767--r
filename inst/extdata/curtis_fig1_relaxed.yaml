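description: >
  Idealised single-insecticide scenario with an interruption of selection:
  insecticide 1 is deployed for generations 1-3, deployment then lapses
  (no insecticide encountered) for generations 4-12, and resumes from
  generation 13. The resistance allele starts at 0.1%; with no fitness
  costs its frequency is frozen during the relaxed span.
locus1:
  effectiveness: 1.0
  dominance: 1.0
  rr_restoration: 1.0
  cost: 0.0
  cost_dominance: 0.0
locus2:
  effectiveness: 1.0
  dominance: 1.0
  rr_restoration: 1.0
  cost: 0.0
  cost_dominance: 0.0
exposure:
  exposure: 0.9
  male_exposure_prop: 1.0
  correct_mix_deploy: 1.0
simulation:
  start_freq_1: 0.001
  start_freq_2: 0.0
  recombination: 0.5
  threshold: 0.5
  max_generations: 500
schedule:
- from: 1
  to: 3
  strategy: single
  insecticide: 1
- from: 4
  to: 12
  strategy: none
- from: 13
  to: 20
  strategy: single
  insecticide: 1
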