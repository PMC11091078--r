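name	smiles	class
galangin	O=c1c(O)c(-c2ccccc2)oc2cc(O)cc(O)c12	flavonoid
chrysin	O=c1cc(-c2ccccc2)oc2cc(O)cc(O)c12	flavonoid
apigenin	O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12	flavonoid
luteolin	O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12	flavonoid
kaempferol	O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12	flavonoid
quercetin	O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12	flavonoid
myricetin	O=c1c(O)c(-c2cc(O)c(O)c(O)c2)oc2cc(O)cc(O)c12	flavonoid
formononetin	COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1	flavonoid
daidzein	Oc1ccc(-c2coc3cc(O)ccc3c2=O)cc1	flavonoid
genistein	Oc1ccc(-c2coc3cc(O)cc(O)c3c2=O)cc1	flavonoid
naringenin	O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c21	flavonoid
hesperetin	COc1ccc(C2CC(=O)c3c(O)cc(O)cc3O2)cc1O	flavonoid
catechin	OC1Cc2c(O)cc(O)cc2OC1c1ccc(O)c(O)c1	flavonoid
resveratrol	Oc1ccc(C=Cc2cc(O)cc(O)c2)cc1	stilbene
pterostilbene	COc1cc(C=Cc2ccc(O)cc2)cc(OC)c1	stilbene
pinosylvin	Oc1cc(O)cc(C=Cc2ccccc2)c1	stilbene
piceatannol	Oc1ccc(C=Cc2cc(O)cc(O)c2)cc1O	stilbene
rotundine	COc1ccc2c(c1OC)CN1CCc3cc(OC)c(OC)cc3C1C2	other
vanillin	COc1cc(C=O)ccc1O	other
acetophenone	CC(=O)c1ccccc1	other
hexan-2-one	CCCCC(C)=O	other
coumarin	O=c1ccc2ccccc2o1	other
ferulic_acid	COc1cc(C=CC(=O)O)ccc1O	other
methyl_benzoate	COC(=O)c1ccccc1	other
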