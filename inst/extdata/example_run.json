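{
  "model": { "name": "vdw-water", "r_c": 0.8412, "kappa": 0.01 },
  "system": { "N": 1000, "T": 500, "liquid_density": 66.5,
              "overall_density": 33.3 },
  "protocol": { "ensemble": "nvt", "n_equil_cycles": 400,
                "n_prod_cycles": 1200, "sample_every": 10, "seed": 1 },
  "comment": "direct-coexistence slab of the water-like vdW fluid at T/Tc = 0.77; consumed by `ldpmc simulate --config example_run.json`"
}
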