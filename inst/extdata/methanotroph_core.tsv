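# model: methanotroph_core
# objective: biomass
id	name	equation	reversibility	lower_bound	upper_bound	gene_association
pMMO1	Particulate methane monooxygenase (cytochrome-c coupled)	ch4_c0 + o2_c0 + 2 cytcred_c0 + 2 h_c0 -> meoh_c0 + h2o_c0 + 2 cytcox_c0	irrev	0	1000	
pMMO2	Particulate methane monooxygenase (ubiquinol coupled)	ch4_c0 + o2_c0 + q8h2_c0 -> meoh_c0 + h2o_c0 + q8_c0	irrev	0	1000	
MEDH	Methanol dehydrogenase (cytochrome c)	meoh_c0 + 2 cytcox_c0 -> fald_c0 + 2 cytcred_c0 + 2 h_c0	irrev	0	1000	
FALDH	Formaldehyde dehydrogenase	fald_c0 + nad_c0 + h2o_c0 -> fortm_c0 + nadh_c0 + 2 h_c0	irrev	0	1000	
FDH	Formate dehydrogenase	fortm_c0 + nad_c0 -> co2_c0 + nadh_c0	irrev	0	1000	
FALDTHF	Formaldehyde-tetrahydrofolate condensation	fald_c0 + thf_c0 <=> mlthf_c0 + h2o_c0	rev	-1000	1000	
CPLX1	NADH dehydrogenase (complex I)	nadh_c0 + 5 h_c0 + q8_c0 -> nad_c0 + q8h2_c0 + 4 h_p0	irrev	0	1000	
NDH2	NADH dehydrogenase, non-proton-pumping (NDH-2)	nadh_c0 + h_c0 + q8_c0 -> nad_c0 + q8h2_c0	irrev	0	1000	
rxn10113_c0	Ubiquinol-cytochrome c oxidoreductase (complex III)	q8h2_c0 + 2 cytcox_c0 + 2 h_c0 -> q8_c0 + 2 cytcred_c0 + 4 h_p0	irrev	0	1000	
CPLX4	Cytochrome c oxidase (complex IV)	2 cytcred_c0 + 0.5 o2_c0 + 4 h_c0 -> 2 cytcox_c0 + h2o_c0 + 2 h_p0	irrev	0	1000	
ATPS	ATP synthase	adp_c0 + pi_c0 + 4 h_p0 <=> atp_c0 + h2o_c0 + 3 h_c0	rev	-1000	1000	
NGAM	Non-growth-associated ATP maintenance	atp_c0 + h2o_c0 -> adp_c0 + pi_c0 + h_c0	irrev	0	1000	
LEAK	Membrane proton leak	h_p0 -> h_c0	irrev	0	1000	
GLYS	Glycine synthase (reverse glycine cleavage system)	co2_c0 + nh4_c0 + mlthf_c0 + nadh_c0 -> gly_c0 + thf_c0 + nad_c0	irrev	0	1000	
SHMT	Serine hydroxymethyltransferase	gly_c0 + mlthf_c0 + h2o_c0 -> ser_c0 + thf_c0	irrev	0	1000	
SGAT	Serine-glyoxylate aminotransferase	ser_c0 + glx_c0 <=> hpyr_c0 + gly_c0	rev	-1000	1000	
GLYAT	Glyoxylate amination to glycine (transaminase, net)	glx_c0 + nh4_c0 + nadh_c0 + h_c0 -> gly_c0 + nad_c0 + h2o_c0	irrev	0	1000	
HPR	Hydroxypyruvate reductase	hpyr_c0 + nadh_c0 + h_c0 -> glyc_c0 + nad_c0	irrev	0	1000	
GLYCK	Glycerate kinase	glyc_c0 + atp_c0 -> pg2_c0 + adp_c0 + h_c0	irrev	0	1000	
ENO	Enolase	pg2_c0 <=> pep_c0 + h2o_c0	rev	-1000	1000	
PPC	Phosphoenolpyruvate carboxylase	pep_c0 + co2_c0 + h2o_c0 -> oaa_c0 + pi_c0 + h_c0	irrev	0	1000	
MDH	Malate dehydrogenase	oaa_c0 + nadh_c0 + h_c0 <=> mal_c0 + nad_c0	rev	-1000	1000	
MTK	Malate thiokinase	mal_c0 + atp_c0 + coa_c0 -> malcoa_c0 + adp_c0 + pi_c0	irrev	0	1000	
MCL1	Malyl-CoA lyase (malyl-CoA activity)	malcoa_c0 <=> accoa_c0 + glx_c0	rev	-1000	1000	mclA
GLXO	Glyoxylate oxidase (to oxalate)	glx_c0 + nad_c0 + h2o_c0 -> oxa_c0 + nadh_c0 + 2 h_c0	irrev	0	1000	
OXADC	Oxalate decarboxylase	oxa_c0 + h_c0 -> fortm_c0 + co2_c0	irrev	0	1000	
CS	Citrate synthase	accoa_c0 + oaa_c0 + h2o_c0 -> cit_c0 + coa_c0 + h_c0	irrev	0	1000	
ACONT	Aconitase	cit_c0 <=> icit_c0	rev	-1000	1000	
ICDH	Isocitrate dehydrogenase	icit_c0 + nad_c0 -> akg_c0 + co2_c0 + nadh_c0	irrev	0	1000	
AKGDH	2-Oxoglutarate dehydrogenase	akg_c0 + coa_c0 + nad_c0 -> succoa_c0 + co2_c0 + nadh_c0	irrev	0	1000	
SUCOAS	Succinyl-CoA synthetase	succoa_c0 + adp_c0 + pi_c0 <=> succ_c0 + coa_c0 + atp_c0	rev	-1000	1000	
SUCD	Succinate dehydrogenase	succ_c0 + q8_c0 -> fum_c0 + q8h2_c0	irrev	0	1000	
FUM	Fumarase	fum_c0 + h2o_c0 <=> mal_c0	rev	-1000	1000	
PDH	Pyruvate dehydrogenase	pyr_c0 + coa_c0 + nad_c0 -> accoa_c0 + co2_c0 + nadh_c0	irrev	0	1000	
PHAA	Acetyl-CoA acetyltransferase (thiolase, condensation)	2 accoa_c0 -> aacoa_c0 + coa_c0	irrev	0	1000	
PHAB	Acetoacetyl-CoA reductase	aacoa_c0 + nadh_c0 + h_c0 <=> hbcoa_c0 + nad_c0	rev	-1000	1000	
PHAC	PHB polymerase	hbcoa_c0 -> phb_c0 + coa_c0	irrev	0	1000	
PHB_DEG	PHB depolymerase + 3-hydroxybutyryl-CoA activation (lumped)	phb_c0 + coa_c0 + atp_c0 + h2o_c0 -> hbcoa_c0 + adp_c0 + pi_c0 + h_c0	irrev	0	1000	
ECH	Enoyl-CoA hydratase	hbcoa_c0 <=> b2coa_c0 + h2o_c0	rev	-1000	1000	
CCR	Crotonyl-CoA carboxylase/reductase	b2coa_c0 + co2_c0 + nadh_c0 -> emcoa_c0 + nad_c0	irrev	0	1000	
ECM	Ethylmalonyl-CoA mutase	emcoa_c0 <=> mscoa_c0	rev	-1000	1000	
MSD	Methylsuccinyl-CoA dehydrogenase	mscoa_c0 + q8_c0 -> mescoa_c0 + q8h2_c0	irrev	0	1000	
MCH	Mesaconyl-CoA hydratase	mescoa_c0 + h2o_c0 <=> mmalcoa_c0	rev	-1000	1000	
MCL2	Malyl-CoA lyase (L-erythro-3-methylmalyl-CoA activity)	mmalcoa_c0 -> glx_c0 + ppcoa_c0	irrev	0	1000	mclA
PCC	Propionyl-CoA carboxylase	ppcoa_c0 + hco3_c0 + atp_c0 -> mmcoa_c0 + adp_c0 + pi_c0 + h_c0	irrev	0	1000	
MMM	Methylmalonyl-CoA mutase	mmcoa_c0 <=> succoa_c0	rev	-1000	1000	
HCO3E	Carbonic anhydrase	co2_c0 + h2o_c0 <=> hco3_c0 + h_c0	rev	-1000	1000	
ME	Malic enzyme	mal_c0 + nad_c0 -> pyr_c0 + co2_c0 + nadh_c0	irrev	0	1000	
ACK	Phosphotransacetylase + acetate kinase (lumped)	accoa_c0 + adp_c0 + pi_c0 -> ac_c0 + coa_c0 + atp_c0	irrev	0	1000	
ALS	Acetolactate synthase	2 pyr_c0 + h_c0 -> alac_c0 + co2_c0	irrev	0	1000	
ALDC	Acetolactate decarboxylase	alac_c0 + h_c0 -> actn_c0 + co2_c0	irrev	0	1000	
BTDD	Butane-2,3-diol dehydrogenase	actn_c0 + nadh_c0 + h_c0 <=> btd_c0 + nad_c0	rev	-1000	1000	
NASA	Assimilatory nitrate reductase	no3_c0 + nadh_c0 + h_c0 -> no2_c0 + nad_c0 + h2o_c0	irrev	0	1000	
NASB	Assimilatory nitrite reductase (to ammonium)	no2_c0 + 3 nadh_c0 + 5 h_c0 -> nh4_c0 + 3 nad_c0 + 2 h2o_c0	irrev	0	1000	
NAR	Nitrate reductase	no3_c0 + q8h2_c0 + 2 h_c0 -> no2_c0 + h2o_c0 + q8_c0 + 2 h_p0	irrev	0	1000	
NIR	Nitrite reductase	no2_c0 + cytcred_c0 + 2 h_c0 -> no_c0 + h2o_c0 + cytcox_c0	irrev	0	1000	
NOR	Nitric oxide reductase	2 no_c0 + 2 cytcred_c0 + 2 h_c0 -> n2o_c0 + h2o_c0 + 2 cytcox_c0	irrev	0	1000	
NOS	Nitrous oxide reductase	n2o_c0 + 2 cytcred_c0 + 2 h_c0 -> n2_c0 + h2o_c0 + 2 cytcox_c0	irrev	0	1000	
CH4t	ch4 transport	ch4_e0 <=> ch4_c0	rev	-1000	1000	
EX_ch4_e0	ch4 exchange	ch4_e0 <=> 	rev	-1000	1000	
O2t	o2 transport	o2_e0 <=> o2_c0	rev	-1000	1000	
EX_o2_e0	o2 exchange	o2_e0 <=> 	rev	-1000	1000	
CO2t	co2 transport	co2_e0 <=> co2_c0	rev	-1000	1000	
EX_co2_e0	co2 exchange	co2_e0 <=> 	rev	-1000	1000	
NH4t	nh4 transport	nh4_e0 <=> nh4_c0	rev	-1000	1000	
EX_nh4_e0	nh4 exchange	nh4_e0 -> 	irrev	0	1000	
NO3t	no3 transport	no3_e0 <=> no3_c0	rev	-1000	1000	
EX_no3_e0	no3 exchange	no3_e0 <=> 	rev	-1000	1000	
ACt	ac transport	ac_e0 <=> ac_c0	rev	-1000	1000	
EX_ac_e0	ac exchange	ac_e0 -> 	irrev	0	1000	
BTDt	btd transport	btd_e0 <=> btd_c0	rev	-1000	1000	
EX_btd_e0	btd exchange	btd_e0 -> 	irrev	0	1000	
N2t	n2 transport	n2_e0 <=> n2_c0	rev	-1000	1000	
EX_n2_e0	n2 exchange	n2_e0 -> 	irrev	0	1000	
H2Ot	h2o transport	h2o_e0 <=> h2o_c0	rev	-1000	1000	
EX_h2o_e0	h2o exchange	h2o_e0 <=> 	rev	-1000	1000	
Ht	h transport	h_e0 <=> h_c0	rev	-1000	1000	
EX_h_e0	h exchange	h_e0 <=> 	rev	-1000	1000	
EX_phb_c0	PHB storage pool	phb_c0 -> 	irrev	0	1000	
biomass	Biomass synthesis	3 accoa_c0 + 6.6 ser_c0 + 1.2 gly_c0 + 1.2 akg_c0 + 1.2 oaa_c0 + 4.8 nh4_c0 + 24.651 nadh_c0 + 40 atp_c0 + 40 h2o_c0 -> 3 coa_c0 + 24.651 nad_c0 + 40 adp_c0 + 40 pi_c0 + 40 h_c0 + biomass_c0	irrev	0	1000	
DM_biomass_c0	Biomass drain	biomass_c0 -> 	irrev	0	1000	
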