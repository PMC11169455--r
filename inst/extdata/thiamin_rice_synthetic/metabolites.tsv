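id	name	compartment	initial_conc_nmol_per_L	boundary
AIR_p	5-aminoimidazole ribonucleotide	plastid	17	0
SAM_p	S-adenosylmethionine	plastid	17	0
SAH_p	S-adenosylhomocysteine	plastid	1	0
NAD_p	NAD	plastid	100	1
GLY_p	glycine	plastid	1000	1
ATP_p	ATP	plastid	1000	1
ADP_p	ADP	plastid	500	1
HMP_P_p	hydroxymethylpyrimidine phosphate	plastid	2	0
HMP_PP_p	hydroxymethylpyrimidine diphosphate	plastid	5	0
HET_P_p	hydroxyethylthiazole phosphate	plastid	5	0
HET_p	hydroxyethylthiazole	plastid	0.59999999999999998	0
TMP_p	thiamin monophosphate	plastid	1.5	0
PI_p	inorganic phosphate	plastid	1000	1
TMP_c	thiamin monophosphate	cytosol	1.6000000000000001	0
THM_c	thiamin	cytosol	1	0
TDP_c	thiamin diphosphate	cytosol	1	0
HET_c	hydroxyethylthiazole	cytosol	0.5	0
ATP_c	ATP	cytosol	1000	1
ADP_c	ADP	cytosol	500	1
AMP_c	AMP	cytosol	100	1
PI_c	inorganic phosphate	cytosol	1000	1
TMP_m	thiamin monophosphate	mitochondrion	0.90000000000000002	0
THM_m	thiamin	mitochondrion	0.5	0
TDP_m	thiamin diphosphate	mitochondrion	0.5	0
PI_m	inorganic phosphate	mitochondrion	1000	1
AIR_e	AIR (external)	external	100	1
SAM_e	SAM (external)	external	100	1
HET_e	hydroxyethylthiazole (external)	external	100	1
THM_e	thiamin (external)	external	100	1
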