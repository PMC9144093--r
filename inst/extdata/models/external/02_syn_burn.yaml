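# synthetic stand-in model: burn-injury population (augmented clearance)
name: syn_burn
label: 2
parameters:
  CL: "4.9 * (crcl / 100)^0.7 * (1 + 0.25 * burn)"
  V1: "0.50 * weight * (1 + 0.3 * burn)"
  Q: "8.0"
  V2: "60"
omega:
  names: [CL, V1]
  values: [0.14, 0.0, 0.10]
residual: {add: 1.2, prop: 0.18}
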