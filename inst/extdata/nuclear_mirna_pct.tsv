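mirna	nuclear_pct	conserved
hsa-miR-768-5p	94.17	NA
hsa-miR-768-3p	93.71	NA
hsa-miR-1299	93.17	no
hsa-miR-297	92.72	yes
hsa-miR-663b	92.17	no
hsa-miR-647	89.19	no
hsa-miR-595	88.09	no
hsa-miR-921	83.82	no
hsa-miR-593*	80.62	no
hsa-miR-1183	78.28	no
hsa-miR-664*	75.44	yes
hsa-miR-1275	73.87	no
hsa-miR-574-5p	71.94	yes
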