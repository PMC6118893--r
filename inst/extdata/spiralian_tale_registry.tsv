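# Revised spiralian TALE-class clade registry (clades I-XIX plus
# unclassified sequences), reconciling a prior nine-clade system (origin
# P), sequences described in the SPILE literature (origin M) and newly
# discovered sequences (origin N). 'prior' records the clade a sequence
# was assigned to before this revision; NONE if previously unclassified.
clade	species	sequence	letter	origin	prior
TALE-I	S_lamarcki	Slam_TALE-I_A	A	N	NONE
TALE-I	S_lamarcki	Slam_TALE-I_B	B	N	NONE
TALE-I	S_lamarcki	Slam_TALE-I_C	C	N	NONE
TALE-I	C_teleta	Ctel_1513294_24_8		P	NONE
TALE-I	H_robusta	Hrob_TALE-I		N	NONE
TALE-I	P_dumerilii	Pdum_TALE-I		N	NONE
TALE-I	L_anatina	Lana_TALE-I		N	NONE
TALE-I	C_gigas	Cgi_TALE2		P	NONE
TALE-I	P_fucata	Pfuc_24948_1_11659_JP		P	NONE
TALE-I	L_gigantea	Lgig_1414665_30_1		P	NONE
TALE-I	P_vulgata	Pvul_TALE-I		N	NONE
TALE-II	C_gigas	Cgi_TALE1		P	NONE
TALE-II	P_fucata	Pfuc_13151_1_32296_JP		P	NONE
TALE-III	L_anatina	Lana_TALE-III		N	NONE
TALE-III	C_gigas	Cgi_TALE3		P	NONE
TALE-III	P_fucata	Pfuc_98062_1_56909_JP		P	NONE
TALE-III	N_fuscoviridis	Nfus_SPILE-E		M	NONE
TALE-III	P_vulgata	Pvul_TALE-III		N	NONE
TALE-IV	S_lamarcki	Slam_TALE-IV_A1	A1	N	NONE
TALE-IV	S_lamarcki	Slam_TALE-IV_A2	A2	N	NONE
TALE-IV	S_lamarcki	Slam_TALE-IV_B	B	N	NONE
TALE-IV	S_lamarcki	Slam_TALE-IV_AX	AX	N	NONE
TALE-IV	S_lamarcki	Slam_TALE-IV_AY	AY	N	NONE
TALE-IV	S_kraussi	Skra_SPILE-X	X	M	NONE
TALE-IV	S_kraussi	Skra_SPILE-Y	Y	M	NONE
TALE-IV	C_teleta	Ctel_1526117_32_9	A	P	NONE
TALE-IV	C_teleta	Ctel_1505080_24_4	B	P	NONE
TALE-IV	P_dumerilii	Pdum_TALE-IV_B	B	N	NONE
TALE-IV	P_dumerilii	Pdum_TALE-IV_A	A	N	NONE
TALE-IV	C_gigas	Cgi_TALE7		P	NONE
TALE-IV	C_gigas	Cgi_TALE8		P	NONE
TALE-IV	C_gigas	Cgi_TALE14		P	NONE
TALE-IV	P_fucata	Pfuc_1892_1_66137_JP	A	P	NONE
TALE-IV	P_fucata	Pfuc_6497_1_45448_JP	B	P	TALE-VI
TALE-IV	N_fuscoviridis	Nfus_SPILE-B		M	NONE
TALE-IV	P_vulgata	Pvul_TALE-IV		N	NONE
TALE-V	C_gigas	Cgi_TALE6		P	NONE
TALE-V	P_fucata	Pfuc_255_1_07443_JP		P	NONE
TALE-VI	C_gigas	Cgi_TALE9		P	NONE
TALE-VI	C_gigas	Cgi_TALE11		P	NONE
TALE-VI	C_gigas	Cgi_TALE12		P	NONE
TALE-VI	C_gigas	Cgi_TALE13		P	NONE
TALE-VI	P_fucata	Pfuc_1442_1_22591_JP	A	P	NONE
TALE-VI	P_fucata	Pfuc_22569_1_62158_JP	B	P	NONE
TALE-VI	P_fucata	Pfuc_22555_1_40373_JP	C	P	NONE
TALE-VI	P_fucata	Pfuc_18402_1_40058_JP	D	P	NONE
TALE-VI	P_fucata	Pfuc_10095_1_38990_JP	E	P	NONE
TALE-VI	P_fucata	Pfuc_2547_1_30160_JP	F	P	NONE
TALE-VI	P_fucata	Pfuc_312_1_50785_JP	G	P	NONE
TALE-VII	S_lamarcki	Slam_TALE-VII_A	A	N	NONE
TALE-VII	S_lamarcki	Slam_TALE-VII_B	B	N	NONE
TALE-VII	C_gigas	Cgi_TALE4		P	NONE
TALE-VII	P_fucata	Pfuc_6013_1_23936_JP		P	NONE
TALE-VIII	S_lamarcki	Slam_TALE-VIII_A	A	N	NONE
TALE-VIII	S_lamarcki	Slam_TALE-VIII_B	B	N	NONE
TALE-VIII	S_lamarcki	Slam_TALE-VIII_C	C	N	NONE
TALE-VIII	S_lamarcki	Slam_TALE-VIII_D	D	N	NONE
TALE-VIII	S_lamarcki	Slam_TALE-VIII_E	E	N	NONE
TALE-VIII	S_lamarcki	Slam_TALE-VIII_F	F	N	NONE
TALE-VIII	S_lamarcki	Slam_TALE-VIII_G	G	N	NONE
TALE-VIII	S_lamarcki	Slam_TALE-VIII_H	H	N	NONE
TALE-VIII	S_kraussi	Skra_SPILE-Z		M	NONE
TALE-VIII	C_teleta	Ctel_1505086_31_9	B1	P	NONE
TALE-VIII	C_teleta	Ctel_1505698_31_9	B2	P	NONE
TALE-VIII	C_teleta	Ctel_1499331_27_4	B3	P	NONE
TALE-VIII	C_teleta	Ctel_1499505_38_4	A1	P	TALE-IV
TALE-VIII	C_teleta	Ctel_TALE-VIII_A2	A2	M	NONE
TALE-VIII	C_teleta	Ctel_TALE-VIII_C	C	M	NONE
TALE-IX	C_teleta	Ctel_1518266_30_6	A	P	NONE
TALE-IX	C_teleta	Ctel_1518128_28_9	B	P	NONE
TALE-IX	C_teleta	Ctel_1502937_32_5	C	P	NONE
TALE-X	S_lamarcki	Slam_TALE-X_A	A	N	NONE
TALE-X	S_lamarcki	Slam_TALE-X_B	B	N	NONE
TALE-XI	S_lamarcki	Slam_TALE-XI_A	A	N	NONE
TALE-XI	S_lamarcki	Slam_TALE-XI_B	B	N	NONE
TALE-XI	C_teleta	Ctel_TALE-XI		N	NONE
TALE-XII	C_teleta	Ctel_TALE-XII_A1	A1	M	NONE
TALE-XII	C_teleta	Ctel_TALE-XII_A2	A2	M	NONE
TALE-XII	C_teleta	Ctel_TALE-XII_A3	A3	M	NONE
TALE-XII	C_teleta	Ctel_TALE-XII_B	B	M	NONE
TALE-XIII	S_lamarcki	Slam_TALE-XIII_A	A	N	NONE
TALE-XIII	S_lamarcki	Slam_TALE-XIII_B2	B2	N	NONE
TALE-XIII	C_teleta	Ctel_TALE-XIII		N	NONE
TALE-XIII	L_anatina	Lana_TALE-XIII		N	NONE
TALE-XIII	C_gigas	Cgi_TALE5		P	TALE-?
TALE-XIII	P_vulgata	Pvul_TALE-XIII		N	NONE
TALE-XIV	S_lamarcki	Slam_TALE-XIV		N	NONE
TALE-XIV	P_vulgata	Pvul_TALE-XIV		N	NONE
TALE-XV	L_gigantea	Lgig_1419427_48_9		P	TALE-VI
TALE-XV	N_fuscoviridis	Nfus_SPILE-C		M	NONE
TALE-XV	P_vulgata	Pvul_TALE-XV		N	NONE
TALE-XVI	H_robusta	Hrob_TALE-XVI_A	A	N	NONE
TALE-XVI	H_robusta	Hrob_TALE-XVI_B	B	N	NONE
TALE-XVII	L_gigantea	Lgig_1410135_44_3	A	P	TALE-VI
TALE-XVII	L_gigantea	Lgig_1410138_39_8	B	P	TALE-VI
TALE-XVII	N_fuscoviridis	Nfus_SPILE-A		M	NONE
TALE-XVIII	S_lamarcki	Slam_TALE-XVIII		N	Mkx2
TALE-XVIII	C_teleta	Ctel_TALE-XVIII		M	NONE
TALE-XVIII	L_anatina	Lana_TALE-XVIII		N	NONE
TALE-XVIII	N_fuscoviridis	Nfus_SPILE-D		M	NONE
TALE-XVIII	P_vulgata	Pvul_TALE-XVIII_A	A	N	NONE
TALE-XVIII	P_vulgata	Pvul_TALE-XVIII_B	B	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_A	A	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_B	B	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_C	C	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_D	D	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_E	E	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_F	F	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_G	G	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_H	H	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_I	I	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_J	J	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_K	K	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_L	L	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_M	M	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_N	N	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_O	O	N	NONE
TALE-XIX	H_robusta	Hrob_TALE-XIX_P	P	N	NONE
TALE-?	S_lamarcki	Slam_TALE-orphan_A	A	N	NONE
TALE-?	C_teleta	Ctel_TALE-orphan_A		M	NONE
TALE-?	C_teleta	Ctel_TALE-orphan_C		M	NONE
TALE-?	C_teleta	Ctel_TALE-IV-like		M	NONE
TALE-?	C_teleta	Ctel_TALE-IX-like		M	NONE
TALE-?	P_dumerilii	Pdum_TALE-orphan		N	NONE
TALE-?	C_gigas	Cgi_TALE10		P	TALE-VI
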