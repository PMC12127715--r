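# Sample generator configuration. Any field may be omitted; package defaults
# (the calibrated reference-cohort conditions) fill the gaps.
n: 35170
seed: 1
missingness:
  utapi: 0.50787
  plgf: 0.27793
pe_targets:
  overall: 0.018624
  preterm: 0.0059994
  preterm_sga: 0.0038670
  term: 0.012624
  term_sga: 0.0028149
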