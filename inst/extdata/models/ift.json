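{
  "name": "ift",
  "kind": "mie_tdep",
  "lambda_r": 8,
  "lambda_a": 6,
  "eps_coef": [507.3211334, 0.3599284846, -1.451492021e-03, 9.829909971e-07],
  "sigma_coef": [0.2842405377, 1.707005685e-04, -5.251158395e-07, 4.88246531e-10],
  "T_range": [300, 620],
  "provenance": "Synthetic stand-in for the published surface-tension-oriented parametrization: shares sigma(T) with the 'vle' entry and refits eps(T) to saturated liquid density only (vapour pressure is deliberately unconstrained, mirroring the published model's known weakness); surface tension is matched through the square-gradient kappa(T) calibration, not through these parameters. See scratch/parametrize.R."
}
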