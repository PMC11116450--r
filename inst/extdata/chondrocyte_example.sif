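IL6	+	NFKB
IL8	+	NFKB
TNFa	+	NFKB
IL18	+	NFKB
IL17	+	NFKB
IFNg	+	NFKB
IL4	-	NFKB
TNFa	+	AP1
IL17	+	AP1
IL18	+	AP1
IFNg	+	AP1
IL4	-	AP1
TNFa	-	SOX9
IL6	-	SOX9
IL4	+	SOX9
TNFa	-	FOXO
IL6	-	FOXO
IL8	-	FOXO
IL4	+	FOXO
VEGF	+	HIF2A
IL6	+	HIF2A
VEGF	+	RUNX2
TNFa	+	RUNX2
IL4	+	CREB
VEGF	+	CREB
VEGF	+	CITED2
IL18	-	CITED2
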