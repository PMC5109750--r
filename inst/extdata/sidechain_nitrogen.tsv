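aa	nitrogen_atoms
A	0
C	0
D	0
E	0
F	0
G	0
H	2
I	0
K	1
L	0
M	0
N	1
P	0
Q	1
R	3
S	0
T	0
V	0
W	1
Y	0
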