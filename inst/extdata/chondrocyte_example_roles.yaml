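# Roles for the bundled example chondrocyte-like network. Synthetic,
# illustrative topology; gains/decays use the package defaults
# (h = 10, gamma = 1) unless listed here.
roles:
  IL6: input
  IL8: input
  IL4: input
  TNFa: input
  IL18: input
  IFNg: input
  IL17: input
  VEGF: input
  NFKB: output_tf
  AP1: output_tf
  SOX9: output_tf
  FOXO: output_tf
  HIF2A: output_tf
  RUNX2: output_tf
  CREB: output_tf
  CITED2: output_tf
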