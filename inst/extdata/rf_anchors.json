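{
  "description": "Reading-frame anchor map for germline D segments. For each gene, the germline-relative translation offset (0/1/2, 0-based base at which codons begin) is mapped to the Ichihara-Kurosawa style label I/II/III. Anchors for the bundled mouse genes are calibrated so that RFI is the tyrosine-enriched frame, RFII the valine-bearing hydrophobic frame and RFIII the leucine/arginine/stop-bearing frame of their germline translations. Genes without an entry fall back to 'default'.",
  "default": { "0": "I", "1": "II", "2": "III" },
  "genes": {
    "D1-1": { "2": "I", "0": "II", "1": "III" },
    "D2-2": { "2": "I", "0": "II", "1": "III" }
  }
}
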