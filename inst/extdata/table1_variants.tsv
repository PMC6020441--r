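individual_id	cohort_id	gene	hgvs_c	hgvs_p	consequence	exon_index	exon_count	pop_afs	clinvar	agvgd	mapp	polyphen2	cadd	prior_p	splice_effect_predicted	functional_assay	splice_demonstrated	weight_override	printed_weight
HCH34-001	c34	ATM	c.7327C>G	p.(R2443G)	missense	NA	NA			severe	severe	severe	not_severe	NA	unknown	none	FALSE	NA	0.81
HCH34-002	c34	ATM	c.8734A>G	p.(R2912G)	missense	NA	NA			severe	severe	not_severe	severe	NA	unknown	none	FALSE	NA	0.81
HCH34-003	c34	BRCA2	c.3873del	p.(Q1291Hfs*2)	frameshift	11	27			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH34-004	c34	MSH6	c.3261dup	p.(F1088Lfs*5)	frameshift	5	10			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH34-005	c34	PALB2	c.1240C>T	p.(R414*)	nonsense	4	13			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH34-006	c34	STK11	c.738C>A	p.(Y246*)	nonsense	6	10			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH59-001	c59	ATM	c.1564_1565del	p.(E522Ifs*43)	frameshift	10	63			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH59-002	c59	ATM	c.8734A>G	p.(R2912G)	missense	NA	NA			severe	severe	not_severe	severe	NA	unknown	none	FALSE	NA	0.81
HCH59-003	c59	BRCA1	c.68_69del	p.(E23Vfs*17)	frameshift	2	23			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH59-004	c59	BRCA2	c.3974_3975insTGCT	p.(T1325Cfs*4)	frameshift	11	27			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH59-005	c59	BRCA2	c.8447G>A	p.(G2816D)	missense	NA	NA			severe	not_severe	severe	severe	NA	unknown	none	FALSE	NA	0.81
HCH59-006	c59	CHEK2	c.1159A>G	p.(T387A)	missense	NA	NA			severe	severe	severe	not_severe	NA	unknown	none	FALSE	NA	0.81
HCH59-007	c59	CHEK2	c.1427C>T	p.(T476M)	missense	NA	NA			severe	severe	severe	severe	NA	unknown	damaging	FALSE	NA	0.99
HCH59-008	c59	MRE11A	c.923dupT	p.(M309Hfs*8)	frameshift	8	20			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH59-009	c59	MRE11A	c.1516G>T	p.(E506*)	nonsense	13	20			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH59-010	c59	MSH6	c.3851C>T	p.(T1284M)	missense	NA	NA			severe	severe	severe	severe	0.94	unknown	none	FALSE	NA	0.94
HCH59-011	c59	PALB2	c.2167_2168del	p.(M723Vfs*21)	frameshift	5	13			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH59-007	c59	RAD50	c.3641G>A	p.(R1214H)	missense	NA	NA			severe	not_severe	not_severe	severe	NA	unknown	none	FALSE	NA	NA
HCH59-012	c59	TP53	c.847C>T	p.(R283C)	missense	NA	NA			severe	severe	severe	not_severe	NA	unknown	none	FALSE	NA	0.81
HCH14-001	c14	ATM	c.1402_1406delAAGAG	p.(K468Vfs*17)	frameshift	9	63			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH14-002	c14	ATM	c.2426C>A	p.(S809*)	nonsense	16	63			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH14-003	c14	ATM	c.3993+1G>A	NA	canonical_splice	NA	NA			missing	missing	missing	missing	NA	yes	none	FALSE	NA	NA
HCH14-003	c14	BRCA2	c.6275_6276delTT	p.(L2092Pfs*7)	frameshift	11	27			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH14-004	c14	CDKN2A	c.301G>T	p.(G101W)	missense	NA	NA			severe	severe	severe	severe	NA	unknown	none	FALSE	1	1
HCH14-005	c14	CHEK2	c.349A>G	p.(R117G)	missense	NA	NA			severe	severe	severe	not_severe	NA	unknown	none	FALSE	0.95	0.95
HCH14-006	c14	MSH6	c.1444C>T	p.(R482*)	nonsense	7	10			missing	missing	missing	missing	NA	unknown	none	FALSE	NA	1
HCH14-007	c14	TP53	c.1015G>A	p.(E339K)	missense	NA	NA			severe	not_severe	severe	severe	NA	unknown	none	FALSE	NA	0.81
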