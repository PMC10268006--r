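participant	reversals_per_min
A	8.2
B	16.75
C	6.5
D	16.2
E	11.6
F	8.22
G	10.33
H	3.44
I	11.78
J	10.67
K	4.33
L	1.22
M	0
N	18.33
O	12.11
P	4.56
Q	8.89
R	17.22
S	16.44
T	9.33
U	0.22
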