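# Demo configuration: end-to-end run on a small synthetic fixture.
seed: 11
dataset: synaptosome
thresholds:
  small_rna_tpm: 1000
  mrna_tpm: 50
  replicate_rule: mean
prune: one_shot
network:
  include_lncrna: false
  include_tf: false
simulate: {}
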