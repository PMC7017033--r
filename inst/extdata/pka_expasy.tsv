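# pHsol ionization table
# name: expasy
group	pKa	charge
D	4.05	-1
E	4.45	-1
C	9.0	-1
Y	10.0	-1
K	10.0	1
R	12.0	1
H	5.98	1
Nterm	7.5	1
Cterm	3.55	-1
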