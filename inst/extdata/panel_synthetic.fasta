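>P02768 synthetic carrier for the human serum albumin signature peptide
MKLVNEVTEFAKGGSSGGSSK
>P02769 synthetic carrier for the bovine serum albumin (IS) signature peptide
MKLVNELTEFAKGGSSGGSSK
>P02788 synthetic carrier for the human lactoferrin signature peptide
MKLRPVAAEVYGTERGGSSGGSSK
>P24627 synthetic carrier for the bovine lactoferrin (IS) signature peptide
MKLRPVAAEIYGTKGGSSGGSSK
>P61626 synthetic carrier for the human lysozyme signature peptide
MKSTDYGIFQINSRGGSSGGSSK
>P00698 synthetic carrier for the chicken lysozyme (IS) signature peptide
MKFESNFNTQATNRGGSSGGSSK
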