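variant	canonical
Purine metabolism	Purine metabolism
purines	Purine metabolism
purine	Purine metabolism
Fatty acid oxidation and synthesis	Fatty acid oxidation and synthesis
fatty acid oxidation	Fatty acid oxidation and synthesis
fatty acid metabolism	Fatty acid oxidation and synthesis
Eicosanoid and resolvin metabolism	Eicosanoid and resolvin metabolism
eicosanoids	Eicosanoid and resolvin metabolism
eicosanoid metabolism	Eicosanoid and resolvin metabolism
eicosanoid	Eicosanoid and resolvin metabolism
Ganglioside metabolism	Ganglioside metabolism
gangliosides	Ganglioside metabolism
Phospholipid metabolism	Phospholipid metabolism
phospholipids	Phospholipid metabolism
phospholipid	Phospholipid metabolism
phophoslipids	Phospholipid metabolism
Sphingolipid metabolism	Sphingolipid metabolism
sphingolipids	Sphingolipid metabolism
sphingolipid	Sphingolipid metabolism
sphingolipids/gangliosides	Sphingolipid metabolism
sphingolipids/gangliosides	Ganglioside metabolism
sphingolipids and gangliosides	Sphingolipid metabolism
sphingolipids and gangliosides	Ganglioside metabolism
Microbiome metabolism	Microbiome metabolism
microbiome	Microbiome metabolism
the microbiome	Microbiome metabolism
SAM, SAH, methionine, cysteine, glutathione metabolism	SAM, SAH, methionine, cysteine, glutathione metabolism
SAM/SAH/glutathione	SAM, SAH, methionine, cysteine, glutathione metabolism
SAM/SAH/GSH	SAM, SAH, methionine, cysteine, glutathione metabolism
SAM/SAH/GSH metabolism	SAM, SAH, methionine, cysteine, glutathione metabolism
S-adenosyl methionine (SAM)/S-adenosylhomocysteine (SAH)/glutathione (GSH)	SAM, SAH, methionine, cysteine, glutathione metabolism
S-adenosylmethionine (SAM), S-adenosyl-homocysteine (SAH), and glutathione (GSH) metabolism	SAM, SAH, methionine, cysteine, glutathione metabolism
S-adenosylmethionine/homocysteine/glutathione (SAM/SAH/GSH) metabolism	SAM, SAH, methionine, cysteine, glutathione metabolism
Vitamin B3 (Niacin, NAD+) metabolism	Vitamin B3 (Niacin, NAD+) metabolism
NAD+ metabolism	Vitamin B3 (Niacin, NAD+) metabolism
NAD+	Vitamin B3 (Niacin, NAD+) metabolism
NAD+/H	Vitamin B3 (Niacin, NAD+) metabolism
vitamin B3-NAD+	Vitamin B3 (Niacin, NAD+) metabolism
vitamin B3-NAD+ metabolism	Vitamin B3 (Niacin, NAD+) metabolism
Glycolysis and gluconeogenesis	Glycolysis and gluconeogenesis
glycolysis	Glycolysis and gluconeogenesis
Cholesterol, cortisol, non-gonadal steroid metabolism	Cholesterol, cortisol, non-gonadal steroid metabolism
cholesterol	Cholesterol, cortisol, non-gonadal steroid metabolism
cholesterol metabolism	Cholesterol, cortisol, non-gonadal steroid metabolism
cholesterol/sterol	Cholesterol, cortisol, non-gonadal steroid metabolism
cholesterol/sterols	Cholesterol, cortisol, non-gonadal steroid metabolism
Nitric oxide, superoxide, peroxide metabolism	Nitric oxide, superoxide, peroxide metabolism
reactive oxygen species and nitric oxide (ROS/NO)	Nitric oxide, superoxide, peroxide metabolism
ROS/NO	Nitric oxide, superoxide, peroxide metabolism
nitric oxide and reactive oxygen metabolism	Nitric oxide, superoxide, peroxide metabolism
NO/ROS	Nitric oxide, superoxide, peroxide metabolism
Cardiolipin metabolism	Cardiolipin metabolism
cardiolipin	Cardiolipin metabolism
Bile salt metabolism	Bile salt metabolism
bile acids	Bile salt metabolism
bile salts	Bile salt metabolism
bile acid metabolism	Bile salt metabolism
Branch chain amino acid metabolism	Branch chain amino acid metabolism
branched chain amino acids	Branch chain amino acid metabolism
branched chain amino acid metabolism	Branch chain amino acid metabolism
BCAA	Branch chain amino acid metabolism
Isoleucine, valine, threonine, or methionine metabolism	Isoleucine, valine, threonine, or methionine metabolism
propionate metabolism and propiogenic amino acids (Ile, Val, Thr, and Met)	Isoleucine, valine, threonine, or methionine metabolism
propionate and propiogenic amino acid metabolism (IVTM; Ile, Val, Thr, Met)	Isoleucine, valine, threonine, or methionine metabolism
IVTM	Isoleucine, valine, threonine, or methionine metabolism
Pyrimidine metabolism	Pyrimidine metabolism
pyrimidines	Pyrimidine metabolism
Krebs cycle	Krebs cycle
mitochondrial Krebs cycle	Krebs cycle
Krebs cycle and mitochondrial metabolism	Krebs cycle
Vitamin B6 (pyridoxine) metabolism	Vitamin B6 (pyridoxine) metabolism
vitamin B6-pyridoxine metabolism	Vitamin B6 (pyridoxine) metabolism
vitamin B6-pyridoxine	Vitamin B6 (pyridoxine) metabolism
pyridoxine	Vitamin B6 (pyridoxine) metabolism
Pentose phosphate, gluconate metabolism	Pentose phosphate, gluconate metabolism
pentose phosphate	Pentose phosphate, gluconate metabolism
pentose phosphate pathway	Pentose phosphate, gluconate metabolism
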