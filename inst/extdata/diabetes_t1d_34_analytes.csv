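abbreviation,name,group,precursor_mz,product_mz,polarity,role,istd_abbreviation,co_quantified_group,fragmentor_v,collision_energy_v,cell_accelerator_v
AADA,DL-2-Aminoadipic Acid,amino_acid_related,330.2,160.1,negative,quantifier,AADA-d3,,150,10,1
ADMA,Asymmetric dimethylarginine,amino_acid_related,371.2,201.2,negative,quantifier,ADMA-d7,ADMA and SDMA,150,5,5
ADMA,Asymmetric dimethylarginine,amino_acid_related,371.2,156.1,negative,qualifier,ADMA-d7,ADMA and SDMA,150,20,1
SDMA,Symmetric dimethylarginine,amino_acid_related,371.2,201.2,negative,quantifier,ADMA-d7,ADMA and SDMA,150,5,5
SDMA,Symmetric dimethylarginine,amino_acid_related,371.2,156.1,negative,qualifier,ADMA-d7,ADMA and SDMA,150,20,1
Ala,L-Alanine,amino_acid_related,258.1,88.1,negative,quantifier,Ala-d4,,100,15,3
AzelA,Azelaic Acid,small_organic_acid,187.2,169.0,negative,qualifier,AzelA-d14,,150,10,1
AzelA,Azelaic Acid,small_organic_acid,187.2,125.2,negative,quantifier,AzelA-d14,,150,15,1
b-OHB,L-3-hydroxybutyric Acid,small_organic_acid,103.2,59.2,negative,quantifier,,,100,5,1
CA,Cholic Acid,bile_acid,407.3,407.3,negative,quantifier,CA-d4,,250,0,1
CA,Cholic Acid,bile_acid,407.3,343.3,negative,qualifier,CA-d4,,250,35,3
CDCA,Deoxychenocholic Acid,bile_acid,391.3,391.3,negative,quantifier,CDCA-d4,,250,0,3
Cit,L-Citrulline,amino_acid_related,344.4,174.2,negative,quantifier,Cit-d4,,150,4,7
Crea,Creatinine,other,114.1,86.2,positive,qualifier,,,150,11,4
Crea,Creatinine,other,114.1,44.1,positive,quantifier,,,150,15,4
DCA,Deoxycholic Acid,bile_acid,391.2,345.3,negative,quantifier,DCA-d4,,200,35,4
DCA,Deoxycholic Acid,bile_acid,391.2,327.2,negative,qualifier,DCA-d4,,200,40,4
GBB,Gamma-butyrobetaine,other,147.2,88.1,positive,quantifier,,,100,16,1
GBB,Gamma-butyrobetaine,other,147.2,60.2,positive,qualifier,,,100,13,1
GCA,Glycocholic Acid,bile_acid,464.3,402.1,negative,qualifier,GCA-d4,,250,40,4
GCA,Glycocholic Acid,bile_acid,464.3,74.1,negative,quantifier,GCA-d4,,250,45,7
GCDCA,Glycochenodeoxycholic Acid,bile_acid,448.3,386.3,negative,qualifier,GDCA-d6,GCDCA and GDCA,150,40,2
GCDCA,Glycochenodeoxycholic Acid,bile_acid,448.3,74.2,negative,quantifier,GDCA-d6,GCDCA and GDCA,200,55,2
GDCA,Glycodeoxycholic Acid,bile_acid,448.3,402.1,negative,qualifier,GDCA-d6,GCDCA and GDCA,250,40,2
GDCA,Glycodeoxycholic Acid,bile_acid,448.3,74.2,negative,quantifier,GDCA-d6,GCDCA and GDCA,200,55,2
Gln,L-Glutamine,amino_acid_related,315.3,145.1,negative,quantifier,Gln-d5,,100,9,6
Glu,L-Glutamic Acid,amino_acid_related,316.1,146.1,negative,quantifier,Glu-d5,,100,6,6
Gly,Glycine,amino_acid_related,244.1,74.1,negative,quantifier,Gly-13C-d2,,200,7,4
GUDCA,Glycoursodeoxycholic Acid,bile_acid,448.3,386.0,negative,qualifier,GUDCA-d4,,250,40,2
GUDCA,Glycoursodeoxycholic Acid,bile_acid,448.3,74.1,negative,quantifier,GUDCA-d4,,250,45,2
HCit,L-Homocitrulline,amino_acid_related,358.3,188.1,negative,qualifier,HCit-d4,,200,10,1
HCit,L-Homocitrulline,amino_acid_related,358.3,145.0,negative,quantifier,HCit-d4,,150,25,2
IndS,Indoxyl Sulfate,other,212.0,132.0,negative,quantifier,IndS-d4,,100,15,2
IndS,Indoxyl Sulfate,other,212.0,80.0,negative,qualifier,IndS-d4,,100,20,2
Kynu,L-Kynurenine,amino_acid_related,377.0,316.1,negative,qualifier,Kynu-13C6,,150,5,2
Kynu,L-Kynurenine,amino_acid_related,377.0,207.0,negative,quantifier,Kynu-13C6,,150,5,5
Leu,L-Leucine,amino_acid_related,300.2,130.2,negative,quantifier,Leu-d10,Leu and Ile,100,10,1
Ile,L-Isoleucine,amino_acid_related,300.2,130.2,negative,quantifier,Leu-d10,Leu and Ile,100,10,1
N-MNA,N-methyl-nicotinamide,other,137.1,108.1,positive,qualifier,N-MNA-d4,,100,15,2
N-MNA,N-methyl-nicotinamide,other,137.1,80.2,positive,quantifier,N-MNA-d4,,100,26,2
Phe,L-Phenylalanine,amino_acid_related,334.2,164.0,negative,quantifier,Phe-d5,,100,10,1
Taurine,Taurine,amino_acid_related,294.1,124.1,negative,quantifier,Taurine-d4,,100,10,2
Taurine,Taurine,amino_acid_related,294.1,80.1,negative,qualifier,Taurine-d4,,100,55,2
TCA,Taurocholic Acid,bile_acid,514.3,123.8,negative,qualifier,TCA-d4,,300,65,5
TCA,Taurocholic Acid,bile_acid,514.3,80.2,negative,quantifier,TCA-d4,,300,95,1
TDCA,Taurodeoxycholic Acid,bile_acid,498.3,107.1,negative,qualifier,TCDCA-d9,TDCA and TCDCA,250,80,1
TDCA,Taurodeoxycholic Acid,bile_acid,498.3,80.1,negative,quantifier,TCDCA-d9,TDCA and TCDCA,300,90,1
TCDCA,Taurochenodeoxycholic Acid,bile_acid,498.3,107.1,negative,qualifier,TCDCA-d9,TDCA and TCDCA,250,80,1
TCDCA,Taurochenodeoxycholic Acid,bile_acid,498.3,80.1,negative,quantifier,TCDCA-d9,TDCA and TCDCA,300,90,1
Trp,L-Tryptophan,amino_acid_related,373.2,203.1,negative,quantifier,Trp-d8,,150,7,2
TUDCA,Tauroursodeoxycholic Acid,bile_acid,498.3,107.1,negative,qualifier,TUDCA-d4,,300,65,5
TUDCA,Tauroursodeoxycholic Acid,bile_acid,498.3,80.1,negative,quantifier,TUDCA-d4,,300,85,1
Tyr,L-Tyrosine,amino_acid_related,350.2,180.1,negative,quantifier,Tyr-d7,,100,7,5
UDCA,Ursodeoxycholic Acid,bile_acid,391.3,391.3,negative,quantifier,UDCA-d4,,250,0,4
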