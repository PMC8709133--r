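{
  "SQ20B": {"r_cell_um": 10.6, "r_nucleus_um": 8.1},
  "Hela":  {"r_cell_um": 8.6,  "r_nucleus_um": 5.5},
  "A549":  {"r_cell_um": 7.4,  "r_nucleus_um": 4.8}
}
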