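{
  "name": "ideal",
  "kind": "ideal",
  "provenance": "Ideal gas (a_ex = 0): exact-limit backend for estimator checks."
}
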