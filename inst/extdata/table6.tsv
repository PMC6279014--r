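Time	Start	Cig1/Cdc2	Cig2/Cdc2	Puc1/Cdc2	Cdc2/Cdc13	Ste9	Rum1	Slp1	Cdc2_Tyr15	Wee1/Mik1	Cdc25	PP
1	1	0	0	0	0	1	1	0	0	1	0	0
2	0	1	1	1	0	1	1	0	0	1	0	0
3	0	0	0	0	0	0	0	0	0	1	0	0
4	0	0	0	0	1	0	0	0	0	1	0	0
5	0	0	0	0	1	0	0	0	0	0	1	0
6	0	0	0	0	1	0	0	0	1	0	1	0
7	0	0	0	0	1	0	0	1	1	0	1	0
8	0	0	0	0	0	0	1	1	1	0	1	1
9	0	0	0	0	0	1	1	0	1	1	0	1
10	0	0	0	0	0	1	1	0	0	1	0	0
11	0	0	0	0	0	1	1	0	0	1	0	0
12	0	0	0	0	0	1	1	0	0	1	0	0
13	0	0	0	0	0	1	1	0	0	1	0	0
14	0	0	0	0	0	1	1	0	0	1	0	0
15	0	0	0	0	0	1	1	0	0	1	0	0
16	0	0	0	0	0	1	1	0	0	1	0	0
17	0	0	0	0	0	1	1	0	0	1	0	0
18	0	0	0	0	0	1	1	0	0	1	0	0
19	0	0	0	0	0	1	1	0	0	1	0	0
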