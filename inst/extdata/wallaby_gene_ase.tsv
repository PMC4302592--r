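ensembl_id	gene_name	coverage	paternal_pct	maternal_pct	reported_status
ENSMEUG00000006054	NAA10	8	62	38	Biallelic
ENSMEUG00000012279	SMC6	39	54	46	Biallelic
ENSMEUG00000005589	CHM	6	33	67	Biallelic
ENSMEUG00000008176	HCFC1	10	30	70	Biallelic
ENSMEUG00000004133	HTATSF1	10	40	60	Biallelic
ENSMEUG00000002761	MECP2	7	57	43	Biallelic
ENSMEUG00000015172	VAMP7	30	40	60	Biallelic
ENSMEUG00000015485	RAS11LC	30	0	100	PI
ENSMEUG00000015892	RBMX	6	0	100	PI
ENSMEUG00000002871	EBP	50	0	100	PI
ENSMEUG00000012762	LAS1L	5	0	100	PI
ENSMEUG00000007878	OPHN1	7	0	100	PI
ENSMEUG00000011740	PFKFB1	26	0	100	PI
ENSMEUG00000007969	RPS4X	23	0	100	PI
ENSMEUG00000003387	HAUS7	20	0	100	PI
ENSMEUG00000003603	NA	6	0	100	PI
ENSMEUG00000000692	TSPAN6	5	0	100	PI
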