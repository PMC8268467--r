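sample_id	otu1	otu2	otu3	otu4	otu5	otu6	otu7	otu8	otu9	otu10
c1	6	13	16	4	7	18	8	3	7	16
c2	58	59	14	22	47	17	8	12	12	11
c3	21	24	3	6	12	5	3	0	5	8
c4	9	4	4	8	47	17	4	28	5	5
c5	7	7	13	3	5	38	1	14	3	9
c6	29	12	21	24	5	4	5	42	8	5
c7	5	8	4	19	8	14	6	9	19	4
c8	6	6	7	7	3	3	13	25	7	7
c9	8	3	8	37	7	3	4	3	5	8
c10	13	19	17	3	4	3	9	6	12	32
c11	6	6	20	15	4	17	11	5	4	12
c12	6	2	39	10	10	6	17	2	27	15
v1	4	7	7	4	2	3	4	1	1	13
v2	17	10	4	9	10	16	11	9	14	22
v3	14	24	15	27	16	10	34	18	36	9
v4	3	12	9	10	16	7	3	10	12	12
v5	5	6	4	19	7	5	13	4	6	3
v6	6	21	8	6	9	9	12	9	16	16
v7	11	7	20	3	3	14	5	10	7	15
v8	2	2	1	3	2	3	3	2	0	1
v9	6	7	5	6	3	8	18	7	13	6
v10	71	35	131	66	49	82	27	81	96	95
v11	4	3	6	2	1	1	5	5	5	0
v12	4	10	3	5	3	4	2	9	5	2
u1	2	7	1	6	3	19	6	9	5	5
u2	24	8	16	5	5	35	9	2	6	20
u3	30	16	26	17	22	8	11	23	21	17
u4	20	48	9	39	27	22	17	35	28	49
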