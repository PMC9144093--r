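# synthetic stand-in model: continuous renal replacement therapy population
name: syn_crrt
label: 1
parameters:
  CL: "(0.9 + 0.03 * crcl) * (1 - 0.55 * crrt)"
  V1: "0.55 * weight"
  Q: "7.0"
  V2: "50"
omega:
  names: [CL, V1]
  values: [0.12, 0.0, 0.08]
residual: {add: 1.0, prop: 0.20}
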