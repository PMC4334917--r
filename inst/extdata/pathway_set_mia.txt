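# Metabolic pathways of the maternal immune activation (MIA) mouse model
# shared with the Fragile X model (the published shared subset; the MIA
# model's full pathway list is not enumerated in the source).
purines
the microbiome
phospholipid
sphingolipid
cholesterol
bile acids
glycolysis
Krebs cycle
NAD+
pyrimidines
SAM/SAH/glutathione
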