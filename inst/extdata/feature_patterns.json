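[
  {"feature": "A", "mode": "atom",     "smarts": "[#8;X1;+0]"},
  {"feature": "A", "mode": "atom",     "smarts": "[#8;X2;+0]"},
  {"feature": "A", "mode": "atom",     "smarts": "[nX2;+0]"},
  {"feature": "A", "mode": "atom",     "smarts": "[NX1;+0]"},
  {"feature": "A", "mode": "atom",     "smarts": "[NX2;+0;!$(N=O)]"},
  {"feature": "A", "mode": "atom",     "smarts": "[NX3;H0;+0;!$(NC=O);!$(NS=O);!$(N=*);!$(Nc)]"},
  {"feature": "D", "mode": "atom",     "smarts": "[#7;!H0]"},
  {"feature": "D", "mode": "atom",     "smarts": "[#8;!H0]"},
  {"feature": "D", "mode": "atom",     "smarts": "[SX2;!H0]"},
  {"feature": "N", "mode": "centroid", "smarts": "[CX3](=O)[OX1-]"},
  {"feature": "N", "mode": "centroid", "smarts": "[CX3](=O)[OX2H1]"},
  {"feature": "N", "mode": "centroid", "smarts": "[SX4](=O)(=O)[OX1-]"},
  {"feature": "N", "mode": "centroid", "smarts": "[SX4](=O)(=O)[OX2H1]"},
  {"feature": "N", "mode": "atom",     "smarts": "[*-;!$([O-]C=O);!$([O-]S=O)]"},
  {"feature": "P", "mode": "atom",     "smarts": "[*+;!$([N+][O-])]"},
  {"feature": "P", "mode": "atom",     "smarts": "[NX3;H2;+0;$(N[CX4])]"}
]
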