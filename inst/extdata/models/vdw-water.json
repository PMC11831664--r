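{
  "name": "vdw-water",
  "kind": "vdw",
  "a_K_nm3": 21.83625,
  "b_nm3": 0.01,
  "provenance": "Van der Waals fluid with water-like critical constants: b = 0.01 nm^3 gives rho_c = 1/(3b) = 33.33 nm^-3 (998 kg/m^3 / 3), a = 27 b T_c / 8 with T_c = 647 K. Closed-form oracle backend used throughout the test suite."
}
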