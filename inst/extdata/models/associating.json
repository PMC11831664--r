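{
  "name": "associating",
  "kind": "mie",
  "epsilon_over_kB": 266.68,
  "sigma_nm": 0.30555,
  "lambda_r": 17.02,
  "lambda_a": 6,
  "assoc": {
    "epsilon_over_kB": 1985.4,
    "bond_volume_nm3": 0.0010084
  },
  "provenance": "Mie parameters and association energy from the published four-site (2H + 2e) single-bead water parametrization. The association-strength kernel here is the TPT1 contact-value closure Delta = g_HS(d) [exp(eps_HB/T) - 1] K, not the published density-temperature polynomial correlation (coefficients unavailable); the bond volume was therefore refit in-package against the synthetic water saturation table (scratch/parametrize.R), giving %AAD ~2.9 (rho_l) and ~9.5 (p_v) over 300-620 K. Treat the bond volume as synthetic."
}
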