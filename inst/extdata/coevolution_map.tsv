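amino_acid	related_aa
Glu	Gln
Glu	Pro
Glu	Arg
Glu	Asp
Asp	Asn
Asp	Thr
Asp	Lys
Gln	His
Ser	Gly
Ser	Cys
Ser	Trp
Phe	Tyr
Val	Leu
Thr	Ile
Thr	Met
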