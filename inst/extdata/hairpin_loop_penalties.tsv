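loop_len	dg37_kcal_mol
3	3.50
4	3.50
5	3.30
6	4.00
7	4.10
8	4.10
9	4.20
10	4.30
11	4.40
12	4.50
13	4.55
14	4.60
15	4.65
16	4.70
17	4.75
18	4.80
19	4.85
20	4.90
21	4.96
22	5.02
23	5.08
24	5.14
25	5.20
26	5.24
27	5.28
28	5.32
29	5.36
30	5.40
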