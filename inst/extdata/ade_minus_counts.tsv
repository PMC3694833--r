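# Marker-loss (Met-) scoring of rare marker-negative suicide-deletion
# colonies, with junction-flanking PCR on a tested subsample: PCR-positive
# colonies carry an imprecise end-joining junction, PCR-negative ones a
# large deletion.
strain	met_minus	total_colonies	pcr_positive	pcr_tested
wild_type	25	183	17	25
dnl4del	32	141	0	26
K282R	37	140	3	24
D284A	21	140	5	20
K466A	27	190	20	25
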