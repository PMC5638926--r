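pathway	gene_id	excluded
chlorophyll_a	chlB	FALSE
chlorophyll_a	chlD	FALSE
chlorophyll_a	chlE	FALSE
chlorophyll_a	chlG	FALSE
chlorophyll_a	chlH	FALSE
chlorophyll_a	chlI	FALSE
chlorophyll_a	chlL	FALSE
chlorophyll_a	chlM	FALSE
chlorophyll_a	chlN	FALSE
chlorophyll_a	bciB	FALSE
vitamin_b12	cbiA	FALSE
vitamin_b12	cbiB	FALSE
vitamin_b12	cbiC	FALSE
vitamin_b12	cbiD	FALSE
vitamin_b12	cbiE	FALSE
vitamin_b12	cbiF	FALSE
vitamin_b12	cbiG	FALSE
vitamin_b12	cbiH	FALSE
vitamin_b12	cbiJ	FALSE
vitamin_b12	cbiK	FALSE
vitamin_b12	cbiL	FALSE
vitamin_b12	cbiT	FALSE
vitamin_b12	cobA	FALSE
vitamin_b12	cobQ	FALSE
vitamin_b12	cobR	TRUE
vitamin_b12	cobS	FALSE
vitamin_b12	cobT	FALSE
vitamin_b12	cobU	FALSE
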