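[
  {"gene_i": "UBE2C", "gene_j": "FITM1", "tumor_direction": "greater", "control_direction": "less", "rank": 1},
  {"gene_i": "SERPINB5", "gene_j": "ZNF100", "tumor_direction": "greater", "control_direction": "less", "rank": 2},
  {"gene_i": "NUSAP1", "gene_j": "ONECUT1", "tumor_direction": "greater", "control_direction": "less", "rank": 3},
  {"gene_i": "LAMC2", "gene_j": "RBM33", "tumor_direction": "greater", "control_direction": "less", "rank": 4},
  {"gene_i": "BCAR3", "gene_j": "FBXO42", "tumor_direction": "greater", "control_direction": "less", "rank": 5},
  {"gene_i": "CTSE", "gene_j": "PRRC2C", "tumor_direction": "greater", "control_direction": "less", "rank": 6},
  {"gene_i": "HOXB7", "gene_j": "MYO19", "tumor_direction": "greater", "control_direction": "less", "rank": 7},
  {"gene_i": "NUSAP1", "gene_j": "TNKS", "tumor_direction": "greater", "control_direction": "less", "rank": 8},
  {"gene_i": "RRM2", "gene_j": "ONECUT1", "tumor_direction": "greater", "control_direction": "less", "rank": 9}
]
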