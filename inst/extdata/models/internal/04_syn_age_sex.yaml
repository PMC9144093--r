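# synthetic stand-in model
name: syn_age_sex
label: 4
parameters:
  CL: "(4.6 - 0.018 * age) * (1 - 0.12 * sexf)"
  V1: "0.60 * weight"
  Q: "5.2"
  V2: "48"
omega:
  names: [CL, V1]
  values: [0.09, 0.0, 0.06]
residual: {add: 1.0, prop: 0.20}
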