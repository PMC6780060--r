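abbreviation,name,mix_concentration_ng_per_ml
AADA-d3,d3-DL-2-Aminoadipic Acid,10000
ADMA-d7,d7-Asymmetric dimethylarginine,5000
Ala-d4,d4-DL-Alanine,5000
a-OHB-d3,d3-2-Hydroxybutyric Acid,100000
AzelA-d14,d14-Azelaic Acid,5000
b-OHB-d4,d4-3-Hydroxybutyric Acid,100000
CA-d4,d4-Cholic Acid,500
CDCA-d4,d4-Deoxychenocholic Acid,500
Cit-d4,d4-Citrulline,500
Crea-d5,d5-Creatinine,10000
DCA-d4,d4-Deoxycholic Acid,500
GBB-d9,d9-Gamma-butyrobetaine,500
GCA-d4,d4-Glycocholic Acid,250
GCDCA-d4,d4-Glychochenodeoxycholic Acid,5000
GDCA-d6,d6-Glycodeoxycholic Acid,30000
Gln-d5,d5-Glutamine,30000
Glu-d5,d5-L-Glutamic Acid,5000
Gly-13C-d2,Glycine-1-13C-2-2-d2,5000
GUDCA-d4,d4-Glycoursodeoxycholic Acid,5000
HCit-d4,2H4-L-Homocitrulline,5000
IndS-d4,d4-Indoxyl Sulfate,5000
Kynu-13C6,13C6-Kynurenine,30000
Leu-d10,d10-L-Leucine,5000
Ile-d10,d10-Isoleucine,5000
N-MNA-d4,d4-N-methyl-nicotinamide,250
Phe-d5,d5-L-Phenylalanine,500
Taurine-d4,d4-Taurine,500
TCA-d4,d4-Taurocholic Acid,500
TCDCA-d9,d9-Taurochenodeoxycholic Acid,500
Trp-d8,d8-Tryptophan,5000
TUDCA-d4,d4-Tauroursodeoxycholic Acid,250
Tyr-d7,d7-Tyrosine,5000
UDCA-d4,d4-Ursodeoxycholic Acid,250
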