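{
  "fixture": "toy-6-genus",
  "seed": 1,
  "n_genera": 6,
  "n_samples": 12,
  "planted": [
    {
      "genus_a": "gA",
      "genus_b": "gB",
      "delta": 0.25
    },
    {
      "genus_a": "gC",
      "genus_b": "gD",
      "delta": -0.25
    }
  ]
}
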