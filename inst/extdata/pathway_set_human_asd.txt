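# Metabolic pathway disturbances reported in human autism spectrum
# disorder, as enumerated in the cross-model comparison (verbatim variant
# spellings; resolved through the synonym table).  Bile acids, cardiolipin
# and the pentose phosphate pathway are absent: bile acids have not yet
# been studied in human autism.
purines
microbiome
sphingolipids
phophoslipids
cholesterol/sterols
glycolysis
Krebs cycle
vitamin B3-NAD+
pyrimidines
S-adenosyl methionine (SAM)/S-adenosylhomocysteine (SAH)/glutathione (GSH)
fatty acid oxidation
eicosanoids
gangliosides
reactive oxygen species and nitric oxide (ROS/NO)
branched chain amino acids
propionate metabolism and propiogenic amino acids (Ile, Val, Thr, and Met)
vitamin B6-pyridoxine metabolism
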