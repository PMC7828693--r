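id	name	compartment	carbons	role	pair	reduced
glc_e	D-glucose	extracellular	6	boundary		0
o2_e	molecular oxygen	extracellular	0	boundary		0
co2_e	carbon dioxide	extracellular	1	boundary		0
ac_e	acetate	extracellular	2	boundary		0
etoh_e	ethanol	extracellular	2	boundary		0
succ_e	succinate	extracellular	4	boundary		0
prop_e	propionate	extracellular	3	boundary		0
pyr_e	pyruvate	extracellular	3	boundary		0
glyc_e	glycerol	extracellular	3	boundary		0
glc_g	D-glucose	glycosome	6	substrate		0
g6p_g	glucose 6-phosphate	glycosome	6	substrate		0
f6p_g	fructose 6-phosphate	glycosome	6	substrate		0
fdp_g	fructose 1,6-bisphosphate	glycosome	6	substrate		0
dhap_g	dihydroxyacetone phosphate	glycosome	3	substrate		0
gap_g	glyceraldehyde 3-phosphate	glycosome	3	substrate		0
bpg13_g	1,3-bisphosphoglycerate	glycosome	3	substrate		0
pg3_g	3-phosphoglycerate	glycosome	3	substrate		0
pep_g	phosphoenolpyruvate	glycosome	3	substrate		0
oaa_g	oxaloacetate	glycosome	4	substrate		0
mal_g	L-malate	glycosome	4	substrate		0
fum_g	fumarate	glycosome	4	substrate		0
succ_g	succinate	glycosome	4	substrate		0
g3p_g	glycerol 3-phosphate	glycosome	3	substrate		0
glyc_g	glycerol	glycosome	3	substrate		0
co2_g	carbon dioxide	glycosome	1	substrate		0
atp_g	ATP	glycosome	0	cofactor		0
adp_g	ADP	glycosome	0	cofactor		0
amp_g	AMP	glycosome	0	cofactor		0
nad_g	NAD+	glycosome	0	cofactor	nad	0
nadh_g	NADH	glycosome	0	cofactor	nad	1
pg3_c	3-phosphoglycerate	cytosol	3	substrate		0
pg2_c	2-phosphoglycerate	cytosol	3	substrate		0
pep_c	phosphoenolpyruvate	cytosol	3	substrate		0
pyr_c	pyruvate	cytosol	3	substrate		0
acald_c	acetaldehyde	cytosol	2	substrate		0
etoh_c	ethanol	cytosol	2	substrate		0
co2_c	carbon dioxide	cytosol	1	substrate		0
atp_c	ATP	cytosol	0	cofactor		0
adp_c	ADP	cytosol	0	cofactor		0
nad_c	NAD+	cytosol	0	cofactor	nad	0
nadh_c	NADH	cytosol	0	cofactor	nad	1
pyr_m	pyruvate	mitochondrion	3	substrate		0
accoa_m	acetyl-CoA	mitochondrion	2	substrate		0
ac_m	acetate	mitochondrion	2	substrate		0
succ_m	succinate	mitochondrion	4	substrate		0
succoa_m	succinyl-CoA	mitochondrion	4	substrate		0
mmcoa_r_m	(R)-methylmalonyl-CoA	mitochondrion	4	substrate		0
mmcoa_s_m	(S)-methylmalonyl-CoA	mitochondrion	4	substrate		0
ppcoa_m	propionyl-CoA	mitochondrion	3	substrate		0
prop_m	propionate	mitochondrion	3	substrate		0
fum_m	fumarate	mitochondrion	4	substrate		0
mal_m	L-malate	mitochondrion	4	substrate		0
oaa_m	oxaloacetate	mitochondrion	4	substrate		0
cit_m	citrate	mitochondrion	6	substrate		0
akg_m	2-oxoglutarate	mitochondrion	5	substrate		0
co2_m	carbon dioxide	mitochondrion	1	substrate		0
o2_m	molecular oxygen	mitochondrion	0	substrate		0
dhap_m	dihydroxyacetone phosphate	mitochondrion	3	substrate		0
g3p_m	glycerol 3-phosphate	mitochondrion	3	substrate		0
atp_m	ATP	mitochondrion	0	cofactor		0
adp_m	ADP	mitochondrion	0	cofactor		0
nad_m	NAD+	mitochondrion	0	cofactor	nad	0
nadh_m	NADH	mitochondrion	0	cofactor	nad	1
coa_m	coenzyme A	mitochondrion	0	cofactor		0
q_m	ubiquinone	mitochondrion	0	cofactor	q	0
qh2_m	ubiquinol	mitochondrion	0	cofactor	q	1
cytc_ox_m	cytochrome c (oxidized)	mitochondrion	0	cofactor	cytc	0
cytc_red_m	cytochrome c (reduced)	mitochondrion	0	cofactor	cytc	1
pmf_m	proton-motive coupling unit	mitochondrion	0	cofactor		0
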