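pathway	n_measured	observed_hits	impact	n_increased	n_decreased
Purine metabolism	41	5	27.2	1	4
Fatty acid oxidation and synthesis	39	9	16.8	0	9
Eicosanoid and resolvin metabolism	36	6	14.7	4	2
Ganglioside metabolism	12	6	13.4	6	0
Phospholipid metabolism	115	6	11.5	6	0
Sphingolipid metabolism	72	5	11.1	2	3
Microbiome metabolism	33	3	6.7	1	2
SAM, SAH, methionine, cysteine, glutathione metabolism	22	3	6.7	3	0
Vitamin B3 (Niacin, NAD+) metabolism	8	2	5.2	1	1
Glycolysis and gluconeogenesis	18	2	4.2	0	2
Cholesterol, cortisol, non-gonadal steroid metabolism	29	2	3.2	2	0
Nitric oxide, superoxide, peroxide metabolism	6	1	2.1	1	0
Cardiolipin metabolism	12	1	2.0	0	1
Bile salt metabolism	8	1	1.8	1	0
Branch chain amino acid metabolism	13	1	1.7	1	0
Isoleucine, valine, threonine, or methionine metabolism	4	1	1.7	1	0
Pyrimidine metabolism	31	1	1.6	0	1
Krebs cycle	17	1	1.6	1	0
Vitamin B6 (pyridoxine) metabolism	5	1	1.5	1	0
Pentose phosphate, gluconate metabolism	11	1	1.5	1	0
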