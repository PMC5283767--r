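description: >
  Idealised two-insecticide scenario: each insecticide kills every SS
  homozygote on contact (effectiveness 1), resistance is fully dominant and
  fully restores fitness, there are no fitness costs, the sexes are equally
  exposed (0.9 of the population encounters the deployed insecticide, 0.1
  escapes) and the loci are unlinked. Starting R-allele frequencies 0.01
  (insecticide 1, the 'old' compound) and 0.001 (insecticide 2, the 'new').
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
interaction:
  ab: 1.0
  Ab: 1.0
  aB: 1.0
  AB: 1.0
simulation:
  start_freq_1: 0.01
  start_freq_2: 0.001
  recombination: 0.5
  threshold: 0.5
  max_generations: 500
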