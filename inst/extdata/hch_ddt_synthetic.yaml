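description: >
  SYNTHETIC / INCOMPLETE sketch of the historical HCH + DDT field scenario.
  Only the DDT locus is anchored to published genotype survival values:
  sensitive and resistant homozygotes survive DDT exposure with fitnesses
  0.27 and 0.50, giving effectiveness 0.73 and rr_restoration 0.23/0.73.
  Every other number below (HCH parameters, dominance values, exposure,
  starting frequencies) is a placeholder for illustration, NOT a field
  estimate; replace them before drawing any conclusion.
locus1:
  # DDT: w(SS) = 0.27, w(RR) = 0.50 under exposure
  effectiveness: 0.73
  dominance: 0.5
  rr_restoration: 0.3150684931506849
  cost: 0.0
  cost_dominance: 0.0
locus2:
  # HCH: placeholders
  effectiveness: 1.0
  dominance: 0.5
  rr_restoration: 1.0
  cost: 0.0
  cost_dominance: 0.0
exposure:
  exposure: 0.9
  male_exposure_prop: 1.0
  correct_mix_deploy: 1.0
simulation:
  start_freq_1: 0.1
  start_freq_2: 0.001
  recombination: 0.5
  threshold: 0.5
  max_generations: 500
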