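recording	neutral	sad	fear	happy	disgust
1	59	46	24	18	36
2	17	66	74	64	35
3	58	60	43	43	38
4	16	59	47	32	31
5	57	30	24	14	60
6	46	54	23	29	19
7	41	72	16	13	22
8	18	57	71	59	21
9	55	32	51	29	44
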