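{
  "name": "t_cell_inflamed_gep_unit_weights",
  "aggregation": "weighted_sum_z",
  "genes": [
    {"id": "CCL5", "weight": 1}, {"id": "CD27", "weight": 1},
    {"id": "CD274", "weight": 1}, {"id": "CD276", "weight": 1},
    {"id": "CD8A", "weight": 1}, {"id": "CMKLR1", "weight": 1},
    {"id": "CXCL9", "weight": 1}, {"id": "CXCR6", "weight": 1},
    {"id": "HLA-DQA1", "weight": 1}, {"id": "HLA-DRB1", "weight": 1},
    {"id": "HLA-E", "weight": 1}, {"id": "IDO1", "weight": 1},
    {"id": "LAG3", "weight": 1}, {"id": "NKG7", "weight": 1},
    {"id": "PDCD1LG2", "weight": 1}, {"id": "PSMB10", "weight": 1},
    {"id": "STAT1", "weight": 1}, {"id": "TIGIT", "weight": 1}
  ]
}
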