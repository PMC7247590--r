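{
  "generator": "gvburden",
  "seed": 424242,
  "n_individuals": 20,
  "populations": {
    "label": ["pop_a", "pop_b", "pop_c"],
    "superpopulation": ["AFR", "EAS", "EUR"],
    "proportion": [0.333333333333333, 0.333333333333333, 0.333333333333333]
  },
  "n_genes": 12,
  "core_gene_fraction": 0.25,
  "core_common_variants": 3,
  "core_common_freq": [0.15, 0.3],
  "variants_per_gene": 4,
  "synonymous_per_gene": 1,
  "allele_freq": {
    "shape1": 0.6,
    "shape2": 12,
    "pop_sd": 0.5
  },
  "deleterious_fraction": 0.15,
  "core_deleterious_fraction": 0.5,
  "score_model": {
    "del_shape1": 4,
    "del_shape2": 18,
    "ben_shape1": 30,
    "ben_shape2": 2,
    "causal_shape1": 2,
    "causal_shape2": 38,
    "method_gamma": [1, 0.85, 1.15, 0.9, 1.1, 1],
    "jitter_sd": 0.02,
    "missing_rate": 0.02,
    "phyloP_range": [-5, 10],
    "gerp_range": [-8, 6.2]
  },
  "n_drugs": 20,
  "genes_per_drug": 1.2,
  "n_planted_vdas": 8,
  "fraction_ethnicity_specific": 0.5,
  "linkage_fidelity": 1,
  "marker_freq": [0.08, 0.2],
  "ethnic_marker_freq": [0.15, 0.3],
  "offtarget_marker_freq": 0.01,
  "causal_background_freq": 0.01,
  "n_noise_vdas": 4,
  "n_coding_vdas": 3
}
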