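# Example pipeline configuration (all keys optional; these are the defaults)
group_labels: [Cyto, Syncytio]
pseudocount: 1
alpha: 0.05
min_unique_peptides: 3
unchanged_tolerance: 0
background_mode: column_totals
adjust: none
stage_pseudocounts:
  first_trimester: 0
  third_trimester: 1
columns:
  protein_id: protein_id
  gene: gene
  counts:
    Cyto: avg_unique_peptides_cyto
    Syncytio: avg_unique_peptides_syncytio
expression_columns:
  gene: gene
  tpm:
    CYT: tpm_cyt
    SYN: tpm_syn
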