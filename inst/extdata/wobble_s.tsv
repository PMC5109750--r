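codon3	anticodon34	s	pairing
T	A	0	Watson-Crick
C	G	0	Watson-Crick
A	T	0	Watson-Crick
G	C	0	Watson-Crick
T	G	0.41	G:U wobble
C	A	0.28	I:C (inosine)
A	A	0.9999	I:A (inosine)
G	T	0.68	U:G wobble
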