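{
  "formulation": "mmf",
  "kapop": 0.23,
  "Vpop": 196.43,
  "Clpop": 9.3,
  "beta_Cl_PTP": 0.33,
  "center_PTP": 21,
  "beta_Cl_TDD": 1.27,
  "center_TDD": 1500,
  "omega_ka": 0.27,
  "omega_V": 0.09,
  "omega_Cl": 0.32,
  "gamma_ka": 0.48,
  "gamma_V": 0.33,
  "gamma_Cl": 0.27,
  "error_kind": "proportional",
  "a": 0,
  "b": 0.17
}
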