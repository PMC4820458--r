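phage	family	origin	lifestyle	genome_size_bp	accession
ECP3	Myoviridae	water	lytic	145518	KJ801617
EF24C	Myoviridae	water	lytic	142072	AP009390
EFRM31	Siphoviridae	water	lytic	16945	GU815339
FL3B	Siphoviridae	clinical	lysogenic	40275	GQ478087
EF11	Siphoviridae	clinical	lysogenic	42822	GQ452243
EFACPT1	Siphoviridae	water	lytic	40923	JX193904
EFAP1	Siphoviridae	farm	lytic	21115	FJ792813
VD13	Siphoviridae	human	lytic	55113	KJ094032
IMEEF1	Siphoviridae	water	lytic	57081	KF192053
BC611	Siphoviridae	clinical	lytic	53996	AB712291
SAP6	Siphoviridae	water	lytic	58619	JF731128
EFDG1	Myoviridae	water	lytic	147589	KP339049
FL1C	Siphoviridae	clinical	lysogenic	38721	GQ478083
pp1-V583	Siphoviridae	clinical	lysogenic	37601	AE016830
EF62	Siphoviridae	infant_feces	lysogenic	39505	CP002495
pp3-V583	Siphoviridae	clinical	lysogenic	48701	AE016830
IMEEF3	Siphoviridae	hospital_water	lytic	41687	KF728385
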