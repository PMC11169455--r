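id	enzyme	stoichiometry	law_type	vmax	km	km_a	km_b	k	substrates	reversible	needs_fba	variant
R_THIC	THIC	-1:AIR_p,-1:SAM_p,+1:HMP_P_p,+1:SAH_p	MM2	0.050000000000000003		5	5		AIR_p;SAM_p	0	0	ternary
R_THI1	THI1	-1:NAD_p,-1:GLY_p,+1:HET_P_p	MM1	0.012	20				NAD_p	0	0	ternary
R_TH1_kinase	TH1	-1:HMP_P_p,-1:ATP_p,+1:HMP_PP_p,+1:ADP_p	MM1	0.080000000000000002	2				HMP_P_p	0	0	ternary
R_TH1_synthase	TH1	-1:HMP_PP_p,-1:HET_P_p,+1:TMP_p,+1:PI_p	MM2	0.040000000000000001		2	2		HMP_PP_p;HET_P_p	0	0	ternary
R_TH2_c	TH2	-1:TMP_c,+1:THM_c,+1:PI_c	MM1	0.050000000000000003	5				TMP_c	0	0	ternary
R_TH2_m	TH2	-1:TMP_m,+1:THM_m,+1:PI_m	MM1	0.02	5				TMP_m	0	0	ternary
R_TDPK	TDPK	-1:THM_c,-1:ATP_c,+1:TDP_c,+1:AMP_c	MM1	0.029999999999999999	10				THM_c	0	0	ternary
R_THiM	THiM	-1:HET_p,-1:ATP_p,+1:HET_P_p,+1:ADP_p	MM2	0.02		1	500		HET_p;ATP_p	0	0	ternary
T_AIR	transport	-1:AIR_e,+1:AIR_p	mass_action					0.00020000000000000001	AIR_e	0	0	ternary
T_SAM	transport	-1:SAM_e,+1:SAM_p	mass_action					0.00020000000000000001	SAM_e	0	0	ternary
T_HET	transport	-1:HET_e,+1:HET_c	mass_action					5.0000000000000002e-05	HET_e	0	0	ternary
T_HET_cp	transport	-1:HET_c,+1:HET_p	mass_action					0.01	HET_c	0	0	ternary
T_TMP_pc	transport	-1:TMP_p,+1:TMP_c	mass_action					0.01	TMP_p	0	0	ternary
T_TMP_cm	transport	-1:TMP_c,+1:TMP_m	mass_action					0.002	TMP_c	0	0	ternary
T_TMP_mc	transport	-1:TMP_m,+1:TMP_c	mass_action					0.001	TMP_m	0	0	ternary
T_THM_cm	transport	-1:THM_c,+1:THM_m	mass_action					0.001	THM_c	0	0	ternary
T_THM_mc	transport	-1:THM_m,+1:THM_c	mass_action					0.0050000000000000001	THM_m	0	0	ternary
T_THM_ec	transport	-1:THM_e,+1:THM_c	mass_action					2.0000000000000002e-05	THM_e	0	0	ternary
T_TDP_cm	transport	-1:TDP_c,+1:TDP_m	mass_action					0.001	TDP_c	0	0	ternary
T_TDP_mc	transport	-1:TDP_m,+1:TDP_c	mass_action					0.0001	TDP_m	0	0	ternary
R_AIR_supply	supply	+1:AIR_p	constant_flux					0.01		0	0	ternary
R_SAM_supply	supply	+1:SAM_p	constant_flux					0.01		0	0	ternary
R_SAH_drain	SAHH	-1:SAH_p	mass_action					0.01	SAH_p	0	0	ternary
R_HMP_P_deg	degradation	-1:HMP_P_p	mass_action					0.0001	HMP_P_p	0	0	ternary
R_HMP_PP_deg	degradation	-1:HMP_PP_p	mass_action					0.0001	HMP_PP_p	0	0	ternary
R_HET_P_deg	degradation	-1:HET_P_p	mass_action					0.0001	HET_P_p	0	0	ternary
R_HET_deg_p	degradation	-1:HET_p	mass_action					0.0001	HET_p	0	0	ternary
R_TMP_deg_c	degradation	-1:TMP_c	mass_action					0.00020000000000000001	TMP_c	0	0	ternary
R_THM_deg_c	degradation	-1:THM_c	mass_action					0.00020000000000000001	THM_c	0	0	ternary
R_TDP_TMP_c	phosphatase	-1:TDP_c,+1:TMP_c,+1:PI_c	mass_action					0.0001	TDP_c	0	0	ternary
T_THM_ce	transport	-1:THM_c,+1:THM_e								0	1	
R_TDP_use_c	utilization	-1:TDP_c								0	1	
R_TDP_use_m	utilization	-1:TDP_m								0	1	
R_THM_use_m	utilization	-1:THM_m								0	1	
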