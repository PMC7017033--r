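# pHsol lipophilicity scale
# name: octanol-hh
aa	neutral	charged
A	0.31	0.31
G	0.00	0.00
I	1.80	1.80
L	1.70	1.70
M	1.23	1.23
F	1.79	1.79
P	0.72	0.72
S	-0.04	-0.04
T	0.26	0.26
W	2.25	2.25
V	1.22	1.22
N	-0.60	-0.60
Q	-0.22	-0.22
D	0.20	-2.80
E	0.54	-2.46
C	1.54	-1.46
Y	0.96	-2.04
H	0.13	-1.87
K	0.52	-0.99
R	-0.30	-1.01
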