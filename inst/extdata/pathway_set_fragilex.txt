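# Metabolic pathways altered by suramin treatment in the Fragile X (Fmr1
# knockout) mouse model: the 20 pathways with at least one metabolite at
# VIP >= 1.5 in the KO-Sur vs KO-Sal discrimination.
Purine metabolism
Fatty acid oxidation and synthesis
Eicosanoid and resolvin metabolism
Ganglioside metabolism
Phospholipid metabolism
Sphingolipid metabolism
Microbiome metabolism
SAM, SAH, methionine, cysteine, glutathione metabolism
Vitamin B3 (Niacin, NAD+) metabolism
Glycolysis and gluconeogenesis
Cholesterol, cortisol, non-gonadal steroid metabolism
Nitric oxide, superoxide, peroxide metabolism
Cardiolipin metabolism
Bile salt metabolism
Branch chain amino acid metabolism
Isoleucine, valine, threonine, or methionine metabolism
Pyrimidine metabolism
Krebs cycle
Vitamin B6 (pyridoxine) metabolism
Pentose phosphate, gluconate metabolism
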