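# synthetic stand-in model (not transcribed from any published study)
name: syn_crcl_linear
label: 1
parameters:
  CL: "0.72 + 0.028 * crcl"
  V1: "0.52 * weight"
  Q: "7.3"
  V2: "44"
omega:
  names: [CL, V1]
  values: [0.06, 0.0, 0.05]
residual: {add: 0.8, prop: 0.18}
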