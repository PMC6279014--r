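Time	Phase	Start	Cig1/Cdc2	Cig2/Cdc2	Puc1/Cdc2	Cdc2/Cdc13	Ste9	Rum1	Slp1	Cdc2_Tyr15	Wee1/Mik1	Cdc25	PP
1	Start	1	0	0	0	0	1	1	0	0	1	0	0
2	G1	0	1	1	1	0	1	1	0	0	1	0	0
3	G1/S	0	0	0	0	0	0	0	0	0	1	0	0
4	G2	0	0	0	0	1	0	0	0	0	1	0	0
5	G2	0	0	0	0	1	0	0	0	0	0	1	0
6	G2/M	0	0	0	0	1	0	0	0	1	0	1	0
7	G2/M	0	0	0	0	1	0	0	1	1	0	1	0
8	M	0	0	0	0	0	0	0	1	1	0	1	1
9	M	0	0	0	0	0	1	1	0	1	1	0	1
10	G1	0	0	0	0	0	1	1	0	0	1	0	0
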