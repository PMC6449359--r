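pairing	s	description
WC	0	Watson-Crick codon:anticodon pairing
GU	0.41	anticodon G at position 34 reading codon-third U
IC	0.28	inosine (from A34) reading codon-third C
IA	0.9999	inosine (from A34) reading codon-third A
UG	0.68	anticodon U at position 34 reading codon-third G
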