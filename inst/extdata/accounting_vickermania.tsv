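reaction_id	flux
ex_glc	-1
glct	1
hk	1
pgi	1
pfk	1
fba	1
tpi	1
gapdh_g	2
pgk_g	2
pg3t	2
pgm_c	2
eno_c	2
pyk_c	1
pept	1
pepck_g	1
mdh_g	1
fh_g	1
frd_g	1
succt_gm	1
pyrt_m	1/2
pdh_m	1/2
asct_m	1/2
scl_m	1/2
pdc_c	1/2
adh_c	1/2
nadht_cm	-1/2
mcm_m	1
mce_m	1
pcc_m	1
pct_m	1
act	1/2
etoht	1/2
propt	1
co2t_gc	-1
co2t_mc	3/2
co2t_ce	1
ex_co2	1
ex_ac	1/2
ex_etoh	1/2
ex_prop	1
atpm_g	1
atpm_c	1
atpm_m	3/2
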