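{
  "Ala_M57": {"C": 8, "H": 26, "N": 1, "O": 2, "Si": 2},
  "Gly_M57": {"C": 8, "H": 24, "N": 1, "O": 2, "Si": 2},
  "Ser_M57": {"C": 14, "H": 40, "N": 1, "O": 3, "Si": 3},
  "Thr_M57": {"C": 14, "H": 42, "N": 1, "O": 3, "Si": 3},
  "Asp_M57": {"C": 14, "H": 40, "N": 1, "O": 4, "Si": 3},
  "Glu_M57": {"C": 14, "H": 42, "N": 1, "O": 4, "Si": 3},
  "Phe_M57": {"C": 8, "H": 30, "N": 1, "O": 2, "Si": 2},
  "Val_M57": {"C": 8, "H": 30, "N": 1, "O": 2, "Si": 2}
}
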