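>alpha_synuclein UniProt P37840, 140 aa
MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVATVAEKTK
EQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQLGKNEEGAPQEGILEDMPVDP
DNEAYEMPSEEGYQDYEPEA
>abeta40 amyloid-beta 1-40, UniProt P05067 residues 672-711
DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV
>IAPP human islet amyloid polypeptide, mature 37-mer as an unmodified calculator construct (free termini, titratable Cys)
KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY
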