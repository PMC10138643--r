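stratum	Genome	Ep	PG	CA
RR-1	51	36	44	44
RR-2	84	11	60	63
RR-3	4	3	4	4
RR-NC	6	3	5	5
CPAP1	14	9	14	13
CPAP3	9	8	7	7
CPCFC	1	1	1	1
CPLCP	6	5	6	6
CPLCA	2	2	2	2
CPF	1	0	1	1
CPFL	4	1	4	4
CPT	4	2	4	4
CPG	22	14	22	22
CPH	23	15	21	22
18aa	5	5	2	5
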