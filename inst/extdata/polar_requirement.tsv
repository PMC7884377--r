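amino_acid	pr_corrected	pr_original
Ala	7.0	7.0
Arg	9.1	9.1
Asn	10.0	10.0
Asp	13.0	13.0
Cys	11.5	4.8
Gln	8.6	8.6
Glu	12.5	12.5
Gly	7.9	7.9
His	8.4	8.4
Ile	4.9	4.9
Leu	4.9	4.9
Lys	10.1	10.1
Met	5.3	5.3
Phe	5.0	5.0
Pro	6.6	6.6
Ser	7.5	7.5
Thr	6.6	6.6
Trp	9.9	5.2
Tyr	5.4	5.4
Val	5.6	5.6
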