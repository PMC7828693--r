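enzyme_id	gene_id	copy_number	read_count	length_bp
hk	VIN_SYN_0001	19	48210	1383
pgi	VIN_SYN_0002	2	9050	1674
pfk	VIN_SYN_0003	4	15400	1452
fba	VIN_SYN_0004	3	12800	1119
tpi	VIN_SYN_0005	2	8100	753
gapdh_g	VIN_SYN_0006	39	96500	1080
gapdh_c	VIN_SYN_0007	38	90110	1014
pgk_g	VIN_SYN_0008	5	16900	1260
g3pdh_g	VIN_SYN_0009	2	4100	1065
glyk	VIN_SYN_0010	0	0	1500
adk	VIN_SYN_0011	1	2300	687
pgm	VIN_SYN_0012	2	5200	759
eno	VIN_SYN_0013	3	14100	1290
pyk	VIN_SYN_0014	4	17600	1497
pepck	VIN_SYN_0015	3	11900	1578
mdh_g	VIN_SYN_0016	2	6900	960
mdh_m	VIN_SYN_0017	1	3400	987
fh_g	VIN_SYN_0018	1	2700	1650
fh_m	VIN_SYN_0019	1	2500	1659
frd	VIN_SYN_0020	3	10400	3414
cs	VIN_SYN_0021	1	1900	1404
ogdh	VIN_SYN_0022	1	1700	3060
scl	VIN_SYN_0023	2	7800	1320
sdh1	VIN_SYN_0024	1	2900	1866
sdh2	VIN_SYN_0025	1	2600	852
asct	VIN_SYN_0026	2	8800	1542
pdh	VIN_SYN_0027	2	9400	2700
adh_zn	VIN_SYN_0028	4	21000	1047
pdc	VIN_SYN_0029	3	13200	1692
mce	VIN_SYN_0030	1	2100	480
mcm	VIN_SYN_0031	1	2400	2250
pcc	VIN_SYN_0032	2	5600	2142
aox	VIN_SYN_0033	6	25300	993
c1_nd7	VIN_SYN_0034	1	1500	1203
c1_nduf	VIN_SYN_0035	1	1800	1434
cytb	VIN_SYN_0036	0	0	1080
cyc1	VIN_SYN_0037	0	0	741
risp	VIN_SYN_0038	0	0	822
qcr1	VIN_SYN_0039	0	0	1389
cytc	VIN_SYN_0040	0	0	342
cox1	VIN_SYN_0041	0	0	1674
cox2	VIN_SYN_0042	0	0	630
cox3	VIN_SYN_0043	0	0	810
cox4	VIN_SYN_0044	0	0	1041
cox6	VIN_SYN_0045	0	0	555
atp6	VIN_SYN_0046	1	2000	678
atpB	VIN_SYN_0047	2	6400	1512
g3pq	VIN_SYN_0048	0	0	1800
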