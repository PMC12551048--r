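{
  "formulation": "ecmps",
  "kapop": 0.18,
  "Vpop": 192.42,
  "Clpop": 9.3,
  "beta_Cl_PTP": 0.16,
  "center_PTP": 67,
  "beta_Cl_TDD": 0.77,
  "center_TDD": 1500,
  "omega_ka": 0.36,
  "omega_V": 0.52,
  "omega_Cl": 0.27,
  "gamma_ka": 0.28,
  "gamma_V": 0.52,
  "gamma_Cl": 0.31,
  "error_kind": "combined",
  "a": 0.04,
  "b": 0.06
}
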