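# synthetic stand-in model: heterogeneous ICU population
name: syn_icu
label: 4
parameters:
  CL: "2.2 * (mdrd / 90)^0.9"
  V1: "0.70 * weight"
  Q: "12.0"
  V2: "90"
omega:
  names: [CL, V1]
  values: [0.20, 0.0, 0.12]
residual: {add: 1.5, prop: 0.20}
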