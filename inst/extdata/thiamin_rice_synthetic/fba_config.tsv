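reaction_id	lower	upper	objective
T_AIR	NA	0.02	NA
R_AIR_supply	NA	0.01	NA
T_SAM	NA	0.02	NA
R_SAM_supply	NA	0.01	NA
T_HET	NA	0.005	NA
T_THM_ec	NA	0.002	NA
R_THIC	NA	0.03	NA
R_TH1_synthase	NA	NA	1
R_TDP_use_c	0.002	NA	NA
R_TDP_use_m	0.001	NA	NA
R_THM_use_m	0.001	NA	NA
T_THM_ce	0.001	NA	NA
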