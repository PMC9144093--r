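# synthetic stand-in model
name: syn_crcl_power
label: 2
parameters:
  CL: "3.83 * (crcl / 100)^0.75"
  V1: "0.44 * weight"
  Q: "6.0"
  V2: "38.4"
omega:
  names: [CL, V1, V2]
  values: [0.10, 0.0, 0.08, 0.0, 0.0, 0.12]
residual: {add: 0.5, prop: 0.22}
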