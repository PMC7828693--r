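id	enzyme_no	name	compartment	equation	reversible	lb	ub	enzymes	subsystem	pseudo
hk	1	hexokinase	glycosome	glc_g + atp_g -> g6p_g + adp_g	0	0	100	hk	glycolysis	0
pgi	2	phosphoglucose isomerase	glycosome	g6p_g -> f6p_g	1	-100	100	pgi	glycolysis	0
pfk	3	phosphofructokinase	glycosome	f6p_g + atp_g -> fdp_g + adp_g	0	0	100	pfk	glycolysis	0
fba	4	fructose-bisphosphate aldolase	glycosome	fdp_g -> dhap_g + gap_g	1	-100	100	fba	glycolysis	0
tpi	5	triosephosphate isomerase	glycosome	dhap_g -> gap_g	1	-100	100	tpi	glycolysis	0
gapdh_g	6	glyceraldehyde-3-phosphate dehydrogenase (glycosomal)	glycosome	gap_g + nad_g -> bpg13_g + nadh_g	1	-100	100	gapdh_g	glycolysis	0
pgk_g	7	phosphoglycerate kinase (glycosomal)	glycosome	bpg13_g + adp_g -> pg3_g + atp_g	1	-100	100	pgk_g	glycolysis	0
g3pdh_g	8	glycerol-3-phosphate dehydrogenase (NAD, glycosomal)	glycosome	dhap_g + nadh_g -> g3p_g + nad_g	1	-100	100	g3pdh_g	glycerol_branch	0
glyk_g	9	glycerol kinase	glycosome	glyc_g + atp_g -> g3p_g + adp_g	1	-100	100	glyk	glycerol_branch	0
adk_g	10	adenylate kinase (glycosomal)	glycosome	2 adp_g -> atp_g + amp_g	1	-100	100	adk	glycolysis	0
pgm_c	15	phosphoglycerate mutase	cytosol	pg3_c -> pg2_c	1	-100	100	pgm	glycolysis	0
eno_c	16	enolase	cytosol	pg2_c -> pep_c	1	-100	100	eno	glycolysis	0
pyk_c	17	pyruvate kinase	cytosol	pep_c + adp_c -> pyr_c + atp_c	0	0	100	pyk	glycolysis	0
pepck_g	18	phosphoenolpyruvate carboxykinase	glycosome	pep_g + co2_g + adp_g -> oaa_g + atp_g	0	0	100	pepck	succinate_branch	0
mdh_g	19	malate dehydrogenase (glycosomal)	glycosome	oaa_g + nadh_g -> mal_g + nad_g	1	-100	100	mdh_g	succinate_branch	0
fh_g	20	fumarate hydratase (glycosomal)	glycosome	mal_g -> fum_g	1	-100	100	fh_g	succinate_branch	0
frd_g	21	NADH-dependent fumarate reductase (glycosomal)	glycosome	fum_g + nadh_g -> succ_g + nad_g	0	0	100	frd	succinate_branch	0
cs_m	26	citrate synthase	mitochondrion	accoa_m + oaa_m -> cit_m + coa_m	0	0	100	cs	tca	0
ogdh_m	27	2-oxoglutarate dehydrogenase	mitochondrion	akg_m + nad_m + coa_m -> succoa_m + co2_m + nadh_m	0	0	100	ogdh	tca	0
scl_m	28	succinyl-CoA ligase	mitochondrion	succoa_m + adp_m -> succ_m + atp_m + coa_m	1	-100	100	scl	acetate_branch	0
sdh_m	29	succinate dehydrogenase (complex II)	mitochondrion	succ_m + q_m -> fum_m + qh2_m	0	0	100	sdh1,sdh2	respiratory_chain	0
asct_m	30	acetate:succinate CoA transferase	mitochondrion	accoa_m + succ_m -> ac_m + succoa_m	0	0	100	asct	acetate_branch	0
pdh_m	31	pyruvate dehydrogenase complex	mitochondrion	pyr_m + nad_m + coa_m -> accoa_m + co2_m + nadh_m	0	0	100	pdh	acetate_branch	0
mdh_m	19	malate dehydrogenase (mitochondrial)	mitochondrion	oaa_m + nadh_m -> mal_m + nad_m	1	-100	100	mdh_m	tca	0
fh_m	20	fumarate hydratase (mitochondrial)	mitochondrion	mal_m -> fum_m	1	-100	100	fh_m	tca	0
adh_c	46	Zn-type alcohol dehydrogenase	cytosol	acald_c + nadh_c -> etoh_c + nad_c	1	-100	100	adh_zn	pyruvate_branch	0
pdc_c	47	pyruvate decarboxylase	cytosol	pyr_c -> acald_c + co2_c	0	0	100	pdc	pyruvate_branch	0
mce_m	48	methylmalonyl-CoA epimerase	mitochondrion	mmcoa_r_m -> mmcoa_s_m	1	-100	100	mce	propionate_cycle	0
mcm_m	49	methylmalonyl-CoA mutase	mitochondrion	succoa_m -> mmcoa_r_m	1	-100	100	mcm	propionate_cycle	0
pcc_m	50	propionyl-CoA carboxylase (decarboxylating direction)	mitochondrion	mmcoa_s_m + adp_m -> ppcoa_m + co2_m + atp_m	0	0	100	pcc	propionate_cycle	0
pct_m		propionate CoA-transferase	mitochondrion	ppcoa_m + succ_m -> prop_m + succoa_m	0	0	100	asct	propionate_cycle	0
nadh1_m		NADH dehydrogenase (complex I)	mitochondrion	nadh_m + q_m -> nad_m + qh2_m + pmf_m	0	0	100	c1_nd7,c1_nduf	respiratory_chain	0
cyc3_m		ubiquinol:cytochrome c oxidoreductase (complex III)	mitochondrion	qh2_m + 2 cytc_ox_m -> q_m + 2 cytc_red_m + pmf_m	0	0	100	cytb,cyc1,risp,qcr1,cytc	respiratory_chain	0
cox_m		cytochrome c oxidase (complex IV)	mitochondrion	2 cytc_red_m + 0.5 o2_m -> 2 cytc_ox_m + pmf_m	0	0	100	cox1,cox2,cox3,cox4,cox6,cytc	respiratory_chain	0
aox_m		alternative oxidase	mitochondrion	qh2_m + 0.5 o2_m -> q_m	0	0	100	aox	respiratory_chain	0
atps_m		ATP synthase (complex V), coupling sink at P/O 0	mitochondrion	pmf_m ->	0	0	100	atp6,atpB	respiratory_chain	1
g3pq_m		glycerol-3-phosphate:ubiquinone oxidoreductase (FAD)	mitochondrion	g3p_m + q_m -> dhap_m + qh2_m	0	0	100	g3pq	glycerol_branch	0
nadht_cm		cytosol/mitochondrion NAD(H) redox shuttle	cytosol,mitochondrion	nadh_c + nad_m -> nad_c + nadh_m	1	-100	100		shuttle	1
glct		glucose uptake (to glycosome)	extracellular,glycosome	glc_e -> glc_g	0	0	100		transport	0
pg3t		3-phosphoglycerate export (glycosome to cytosol)	glycosome,cytosol	pg3_g -> pg3_c	1	-100	100		transport	0
pept		phosphoenolpyruvate import (cytosol to glycosome)	cytosol,glycosome	pep_c -> pep_g	1	-100	100		transport	0
pyrt_m		pyruvate transport (cytosol to mitochondrion)	cytosol,mitochondrion	pyr_c -> pyr_m	1	-100	100		transport	0
succt_gm		succinate transport (glycosome to mitochondrion)	glycosome,mitochondrion	succ_g -> succ_m	0	0	100		transport	0
succt_ge		succinate excretion	glycosome,extracellular	succ_g -> succ_e	0	0	100		transport	0
act		acetate excretion	mitochondrion,extracellular	ac_m -> ac_e	0	0	100		transport	0
etoht		ethanol excretion	cytosol,extracellular	etoh_c -> etoh_e	0	0	100		transport	0
propt		propionate excretion	mitochondrion,extracellular	prop_m -> prop_e	0	0	100		transport	0
pyrt_e		pyruvate excretion	cytosol,extracellular	pyr_c -> pyr_e	0	0	100		transport	0
glyct		glycerol excretion	glycosome,extracellular	glyc_g -> glyc_e	0	0	100		transport	0
co2t_gc		CO2 transport (glycosome/cytosol)	glycosome,cytosol	co2_g -> co2_c	1	-100	100		transport	0
co2t_mc		CO2 transport (mitochondrion/cytosol)	mitochondrion,cytosol	co2_m -> co2_c	1	-100	100		transport	0
co2t_ce		CO2 transport (cytosol/extracellular)	cytosol,extracellular	co2_c -> co2_e	1	-100	100		transport	0
o2t		oxygen uptake (to mitochondrion)	extracellular,mitochondrion	o2_e -> o2_m	0	0	100		transport	0
g3pt_gm		glycerol-3-phosphate shuttle transport	glycosome,mitochondrion	g3p_g -> g3p_m	1	-100	100		transport	0
dhapt_mg		dihydroxyacetone phosphate shuttle transport	mitochondrion,glycosome	dhap_m -> dhap_g	1	-100	100		transport	0
ex_glc		glucose exchange	extracellular	glc_e ->	0	-1	0		exchange	0
ex_o2		oxygen exchange	extracellular	o2_e ->	0	-100	0		exchange	0
ex_co2		carbon dioxide exchange	extracellular	co2_e ->	1	-100	100		exchange	0
ex_ac		acetate exchange	extracellular	ac_e ->	0	0	100		exchange	0
ex_etoh		ethanol exchange	extracellular	etoh_e ->	0	0	100		exchange	0
ex_succ		succinate exchange	extracellular	succ_e ->	0	0	100		exchange	0
ex_prop		propionate exchange	extracellular	prop_e ->	0	0	100		exchange	0
ex_pyr		pyruvate exchange	extracellular	pyr_e ->	0	0	100		exchange	0
ex_glyc		glycerol exchange	extracellular	glyc_e ->	0	0	100		exchange	0
atpm_g		ATP drain (glycosome)	glycosome	atp_g -> adp_g	0	0	100		atp_drain	1
atpm_c		ATP drain (cytosol)	cytosol	atp_c -> adp_c	0	0	100		atp_drain	1
atpm_m		ATP drain (mitochondrion)	mitochondrion	atp_m -> adp_m	0	0	100		atp_drain	1
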