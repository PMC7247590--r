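{
  "planted": [
    {
      "marker_id": "rsM00001",
      "causal_id": "rsC00001",
      "drug_id": "D003",
      "gene_id": "G010",
      "ethnicity": "Asian",
      "target_population": "pop_b",
      "linkage_fidelity": 1,
      "causal_latent": 0.0854622140871616
    },
    {
      "marker_id": "rsM00002",
      "causal_id": "rsC00002",
      "drug_id": "D015",
      "gene_id": "G012",
      "ethnicity": "Caucasian",
      "target_population": "pop_c",
      "linkage_fidelity": 1,
      "causal_latent": 0.0322743453786113
    },
    {
      "marker_id": "rsM00003",
      "causal_id": "rsC00003",
      "drug_id": "D019",
      "gene_id": "G005",
      "ethnicity": "African-American",
      "target_population": "pop_a",
      "linkage_fidelity": 1,
      "causal_latent": 0.0951836248188331
    },
    {
      "marker_id": "rsM00004",
      "causal_id": "rsC00004",
      "drug_id": "D013",
      "gene_id": "G008",
      "ethnicity": "Asian",
      "target_population": "pop_b",
      "linkage_fidelity": 1,
      "causal_latent": 0.0312711574181235
    },
    {
      "marker_id": "rsM00005",
      "causal_id": "rsC00005",
      "drug_id": "D006",
      "gene_id": "G007",
      "ethnicity": "Caucasian",
      "target_population": "pop_c",
      "linkage_fidelity": 1,
      "causal_latent": 0.0208281265966987
    },
    {
      "marker_id": "rsM00006",
      "causal_id": "rsC00006",
      "drug_id": "D009",
      "gene_id": "G001",
      "ethnicity": "African-American",
      "target_population": "pop_a",
      "linkage_fidelity": 1,
      "causal_latent": 0.0263196108277118
    },
    {
      "marker_id": "rsM00007",
      "causal_id": "rsC00007",
      "drug_id": "D005",
      "gene_id": "G002",
      "ethnicity": null,
      "target_population": null,
      "linkage_fidelity": 1,
      "causal_latent": 0.151469310568978
    },
    {
      "marker_id": "rsM00008",
      "causal_id": "rsC00008",
      "drug_id": "D011",
      "gene_id": "G001",
      "ethnicity": null,
      "target_population": null,
      "linkage_fidelity": 1,
      "causal_latent": 0.0448943216828248
    }
  ],
  "core_genes": ["G001", "G002", "G003"]
}
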