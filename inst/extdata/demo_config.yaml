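# Demo pipeline configuration: a small synthetic atlas through the
# simulate -> qc -> pseudobulk-de -> clonality stages.
seed: 7
out_dir: demo_output
stages:
  - simulate
  - qc
  - pseudobulk_de
  - clonality
simulate:
  n_donors: 8
  tissue_groups: [BLO, JEJ]
  cells_per_donor_tissue: 40
  n_genes: 400
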