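nucleotide	nitrogen_atoms
A	5
G	5
C	3
T	2
U	2
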