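{
  "name": "BCR-665",
  "analyte": "amosite + crocidolite",
  "certified_value_mil_ffg": 49.0,
  "expanded_uncertainty_mil_ffg": 16,
  "t_factor": 2.45,
  "replicates": {"mean": 49.6, "sd": 7.5, "n": 8},
  "sigma_w0": 7.0,
  "u_meas": 7.4,
  "k": 2
}
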