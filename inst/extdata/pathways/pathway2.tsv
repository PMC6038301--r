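# Ammonia-oxidation pathway 2 (NO-shuttle variant): AMO uses NO as the
# electron shuttle (AMO_NO) instead of quinol; hydroxylamine oxidation by
# CuHAO as in pathway 1. NO consumed by AMO_NO is regenerated from nitrite
# by NIR. See pathway1.tsv for the species conventions and the documented
# NIR / NADH_Synt reconstructions (identical here).
id	name	equation	lb	ub	subsystem	genes
Trans_NH4	Ammonium transporter	nh4 -> nh3 + h_p	0	1000	ammonia oxidation
AMO_NO	Ammonia monooxygenase (NO shuttle)	nh3 + o2 + 2 no + h2o -> nh2oh + 2 hno2	0	1000	ammonia oxidation
HAO	Hydroxylamine oxidoreductase	nh2oh + h2o + 4 pcym -> hno2 + 4 pcyme + 4 h_p	0	1000	ammonia oxidation
QH2_Synt	Quinone reductase (QRED)	2 pcyme + q + 2 h_p -> qh2 + 2 pcym	0	1000	ammonia oxidation
NIR	Nitrite reductase (reconstructed)	hno2 + pcye + h_p -> no + h2o + pcy	0	1000	ammonia oxidation
N2O_spon	Abiotic NO + hydroxylamine reaction	no + nh2oh -> n2o + h2o + h_p	0	1000	ammonia oxidation
Cytbc1	Cytochrome bc1 (complex III)	qh2 + h_c + 2 pcy -> q + 3 h_p + 2 pcye	0	1000	electron transport
Cytaa3	Cytochrome aa3 (complex IV)	2 pcye + 0.5 o2 + 4 h_c -> 2 h_p + h2o + 2 pcy	0	1000	electron transport
ATP_Synt	F0F1 ATP synthase	4 h_p + adp + pi -> 3 h_c + atp + h2o	0	1000	electron transport
NADH_Synt	NADH dehydrogenase, reverse (reconstructed)	qh2 + nad -> nadh + q + h_p	0	1000	electron transport
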