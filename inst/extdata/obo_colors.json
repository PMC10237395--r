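{
  "BFO": "#FFFF00",
  "UBO": "#FFFF00",
  "OBI": "#FFFFFF",
  "PATO": "#2ECC40",
  "GO": "#FF851B",
  "CL": "#0074D9",
  "CHEBI": "#B10DC9",
  "UBERON": "#39CCCC",
  "PR": "#F012BE",
  "SO": "#85144B",
  "IAO": "#AAAAAA",
  "RO": "#DDDDDD",
  "ENVO": "#3D9970",
  "NCBITAXON": "#01FF70",
  "DOID": "#FF4136",
  "HP": "#7FDBFF",
  "MONDO": "#E6739F",
  "FOODON": "#C2A878",
  "AGRO": "#7FB069",
  "GENEPIO": "#6C91BF",
  "OGMS": "#D7263D",
  "NCIT": "#A177FF",
  "UO": "#F4D35E",
  "OMRSE": "#EE964B",
  "CLO": "#4062BB",
  "EFO": "#59C3C3",
  "MP": "#F25F5C",
  "ZFA": "#70C1B3",
  "FMA": "#B2DBBF",
  "VO": "#247BA0",
  "IDO": "#FFA69E",
  "ECO": "#93E1D8",
  "PO": "#62C370",
  "TO": "#A4C639",
  "PECO": "#C8963E",
  "OBCS": "#8D99AE",
  "STATO": "#EF8354",
  "MAXO": "#BC9CB0",
  "OAE": "#9E643C",
  "owl": "#BBBBBB"
}
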