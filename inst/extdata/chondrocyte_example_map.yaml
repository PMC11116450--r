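# Analyte column -> network input node. IL-1RA, MCP1 and leptin are
# measured in the panel but have no input node in the example network.
IL6: IL6
IL8: IL8
IL4: IL4
TNFa: TNFa
IL18: IL18
IFNg: IFNg
IL17: IL17
VEGFA: VEGF
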