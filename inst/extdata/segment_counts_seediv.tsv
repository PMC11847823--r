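recording	neutral	sad	fear	happy
1	32	42	23	49
2	40	52	22	35
3	38	42	12	35
4	36	27	64	12
5	28	54	17	28
6	43	42	44	34
7	36	25	55	34
8	53	44	27	34
9	34	15	46	20
10	27	49	60	12
11	45	44	36	10
12	37	19	46	24
13	41	42	32	48
14	44	45	23	26
15	45	23	16	63
16	22	26	39	19
17	38	51	14	28
18	39	41	39	17
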