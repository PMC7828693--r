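enzyme_id	fig1_no	name
hk	1	hexokinase
pgi	2	phosphoglucose isomerase
pfk	3	phosphofructokinase
fba	4	fructose-bisphosphate aldolase
tpi	5	triosephosphate isomerase
gapdh_g	6	glyceraldehyde-3-phosphate dehydrogenase (glycosomal)
gapdh_c	6	glyceraldehyde-3-phosphate dehydrogenase (cytosolic)
pgk_g	7	phosphoglycerate kinase (glycosomal)
g3pdh_g	8	glycerol-3-phosphate dehydrogenase (NAD, glycosomal)
glyk	9	glycerol kinase
adk	10	adenylate kinase (glycosomal)
pgm	15	phosphoglycerate mutase
eno	16	enolase
pyk	17	pyruvate kinase
pepck	18	phosphoenolpyruvate carboxykinase
mdh_g	19	malate dehydrogenase (glycosomal)
mdh_m	19	malate dehydrogenase (mitochondrial)
fh_g	20	fumarate hydratase (glycosomal)
fh_m	20	fumarate hydratase (mitochondrial)
frd	21	NADH-dependent fumarate reductase
cs	26	citrate synthase
ogdh	27	2-oxoglutarate dehydrogenase
scl	28	succinyl-CoA ligase
sdh1	29	succinate dehydrogenase flavoprotein subunit
sdh2	29	succinate dehydrogenase FeS subunit
asct	30	acetate:succinate CoA transferase
pdh	31	pyruvate dehydrogenase complex
adh_zn	46	Zn-type alcohol dehydrogenase (GroES-like domain)
pdc	47	pyruvate decarboxylase
mce	48	methylmalonyl-CoA epimerase
mcm	49	methylmalonyl-CoA mutase
pcc	50	propionyl-CoA carboxylase
aox	NA	alternative oxidase
c1_nd7	NA	complex I subunit ND7 (mitochondrial-encoded)
c1_nduf	NA	complex I NADH-binding subunit (nuclear-encoded)
cytb	NA	complex III cytochrome b (mitochondrial-encoded)
cyc1	NA	complex III cytochrome c1
risp	NA	complex III Rieske FeS protein
qcr1	NA	complex III core protein
cytc	NA	cytochrome c
cox1	NA	complex IV subunit COXI (mitochondrial-encoded)
cox2	NA	complex IV subunit COXII (mitochondrial-encoded)
cox3	NA	complex IV subunit COXIII (mitochondrial-encoded)
cox4	NA	complex IV subunit 4 (nuclear-encoded)
cox6	NA	complex IV subunit 6 (nuclear-encoded)
atp6	NA	ATP synthase subunit 6 (mitochondrial-encoded)
atpB	NA	ATP synthase F1 beta subunit
g3pq	NA	glycerol-3-phosphate:ubiquinone oxidoreductase (FAD)
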