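stratum	Genome	Ep	PG	He	Mg	FA	MA
RR-1	52	42	41	28	22	15	15
RR-2	92	33	29	11	6	34	39
RR-3	2	2	2	2	2	1	1
RR-NC	11	8	6	7	2	2	3
CPAP1	12	8	4	7	1	6	9
CPAP3	6	6	6	4	5	3	3
CPCFC	3	2	3	2	1	2	3
CPLCP	2	2	1	0	0	1	1
CPLCA	0	0	0	0	0	0	0
CPF	1	1	1	1	1	1	1
CPFL	2	2	1	1	0	1	1
CPT	4	4	4	1	3	2	3
CPG	8	4	3	2	1	3	2
CPH	22	18	17	11	11	15	17
18aa	0	0	0	0	0	0	0
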