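# Re-cleavage scoring of marker-positive suicide-deletion survivor colonies:
# survivors whose repaired allele was re-cut by the inducing endonuclease
# used precise religation.
strain	recleavable	tested_recleavage
wild_type	112	120
dnl4del	120	120
K282R	36	118
D284A	66	117
K466A	190	216
L750X	120	120
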