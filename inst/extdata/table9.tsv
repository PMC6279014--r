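Time	Start	Cig1/Cdc2	Cig2/Cdc2	Puc1/Cdc2	Cdc2/Cdc13	Ste9	Rum1	Slp1	Cdc2_Tyr15	Wee1/Mik1	Cdc25	PP	Sep1	Fkh2	Atf1	Cdc10
1	1	0	0	0	0	1	1	0	0	1	0	0	0	1	0	1
2	0	1	1	1	0	1	1	0	0	1	0	0	0	1	0	1
3	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	1
4	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0	1
5	0	0	0	0	1	0	0	0	0	0	1	0	0	1	0	1
6	0	0	0	0	1	0	0	0	1	0	1	0	1	1	1	1
7	0	0	0	0	1	0	0	1	1	0	1	0	1	1	1	1
8	0	0	0	0	0	0	1	1	1	0	1	1	1	1	1	1
9	0	0	0	0	0	1	1	0	1	1	0	1	1	1	1	1
10	1	0	0	0	0	1	1	0	0	1	0	0	0	1	0	1
11	0	1	1	1	0	1	1	0	0	1	0	0	0	1	0	1
12	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	1
13	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0	1
14	0	0	0	0	1	0	0	0	0	0	1	0	0	1	0	1
15	0	0	0	0	1	0	0	0	1	0	1	0	1	1	1	1
16	0	0	0	0	1	0	0	1	1	0	1	0	1	1	1	1
17	0	0	0	0	0	0	1	1	1	0	1	1	1	1	1	1
18	0	0	0	0	0	1	1	0	1	1	0	1	1	1	1	1
19	1	0	0	0	0	1	1	0	0	1	0	0	0	1	0	1
20	0	1	1	1	0	1	1	0	0	1	0	0	0	1	0	1
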