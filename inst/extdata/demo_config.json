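{
  "seed": 20221202,
  "n_frames": 2000,
  "temperature": 298,
  "bin_width": 0.5,
  "write_frames": false,
  "frame_format": "pdb",
  "residues": "internal",
  "chains": {
    "O-linked": {
      "chain": "GlcA-O-GlcNAc-O-GlcA-O-GlcNAc-O-GlcA-O-GlcNAc-O-GlcA-O-GlcNAc-O-GlcA-O-GlcNAc",
      "mixtures": {
        "GlcNAc": {"4C1": 0.999, "1C4": 0.001},
        "GlcA": {"4C1": 0.96, "1S5": 0.01, "1S3": 0.01, "1,4B": 0.01, "B2,5": 0.01}
      }
    },
    "S-linked": {
      "chain": "GlcA-S-GlcNAc-O-GlcA-S-GlcNAc-O-GlcA-S-GlcNAc-O-GlcA-S-GlcNAc-O-GlcA-S-GlcNAc",
      "mixtures": {
        "GlcNAc": {"4C1": 0.4, "1C4": 0.6},
        "GlcA": {"4C1": 0.72, "1S5": 0.07, "1S3": 0.07, "1,4B": 0.07, "B2,5": 0.07}
      }
    }
  }
}
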