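{
  "generator": "spatscale::sample_city_system + sample_tokens",
  "synthetic": true,
  "n": 60,
  "pop_law": "zipf",
  "zipf_s": 2,
  "family": "C",
  "beta": 1.3,
  "Y": 100000,
  "seed_system": 42,
  "seed_tokens": 43,
  "beta_tolerance": 0.05
}
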