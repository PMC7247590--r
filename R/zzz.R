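utils::globalVariables(c(
  "variant_id", "gene_id", "drug_id", "sample_id", "value", "score",
  "log_sum", "n_genes", "omb", "superpopulation", "ethnicity"
))
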