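accession,protein,species,role,partner
P02768,Albumin,Homo sapiens,analyte,
P02769,IS Albumin,Bos taurus,internal_standard,P02768
P02788,Lactoferrin,Homo sapiens,analyte,
P24627,IS Lactoferrin,Bos taurus,internal_standard,P02788
P61626,Lysozyme,Homo sapiens,analyte,
P00698,IS Lysozyme,Gallus gallus,internal_standard,P61626
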