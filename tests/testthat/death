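{
  "estimator": "ore",
  "x": 7,
  "n": 200,
  "mu_g": 0.122598824686752,
  "se_mu": 0.00535165624256449,
  "ci_mu": [0.112109771193686, 0.133087878179817],
  "delta": -0.0175988246867516,
  "se_delta": 0.0212887822300633,
  "ci_delta": [-0.0593240711323919, 0.0241264217588887],
  "epsilon": "NA",
  "mean_if": -3.9533102879079e-18,
  "diagnostics": {
    "se_flavour": "naive"
  },
  "n_truncated": 0,
  "msm": {},
  "config": {
    "input": "/root/pkg/inst/extdata/nhs_like_synthetic.csv",
    "exposure_a": "proc_meat",
    "exposure_b": "poultry",
    "exposure_c": ["fish", "legumes"],
    "covariates": ["age", "bmi", "smoker", "exercise"],
    "outcome": "death",
    "x": 7,
    "estimator": "ore"
  },
  "package_version": "0.1.0"
}
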