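{
  "name": "vle",
  "kind": "mie_tdep",
  "lambda_r": 8,
  "lambda_a": 6,
  "eps_coef": [727.6667387, -1.146183199, 1.869595217e-03, -1.388372496e-06],
  "sigma_coef": [0.2842405377, 1.707005685e-04, -5.251158395e-07, 4.88246531e-10],
  "T_range": [300, 620],
  "provenance": "Synthetic refit: the published temperature-dependent eps(T), sigma(T) coefficients live in supplementary material that is not available, so (eps, sigma) were refit at each temperature so the lambda_r = 8 Mie monomer EoS reproduces the synthetic water saturation table (rho_l and p_v) exactly, then fitted with cubics (max residual 0.63 K in eps, 5.8e-4 nm in sigma); see scratch/parametrize.R."
}
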