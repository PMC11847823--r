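recording	negative	neutral	positive
1	51	58	58
2	59	46	48
3	59	54	66
4	58	58	59
5	51	58	59
6	51	58	58
7	59	46	48
8	59	54	66
9	58	58	59
10	51	58	59
11	51	58	58
12	59	46	48
13	59	54	66
14	58	58	59
15	51	58	59
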