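1	189374372	190709301	pathref_1_1	any
2	58154222	59370403	pathref_2_1	any
2	74847354	75334605	pathref_2_2	any
2	125522805	126975458	pathref_2_3	any
2	129487533	131221699	pathref_2_4	any
2	238308240	243099444	pathref_2_5	any
3	19273614	19854654	pathref_3_1	any
4	43999200	44596716	pathref_4_1	any
4	58179741	62744625	pathref_4_2	any
4	146802876	148139943	pathref_4_3	any
5	1675593	2207203	pathref_5_1	any
5	45278786	46344867	pathref_5_2	any
5	68857281	70401241	pathref_5_3	any
5	144762149	146569069	pathref_5_4	any
7	1193840	1648496	pathref_7_1	any
7	39127060	39555773	pathref_7_2	any
7	104666521	105109343	pathref_7_3	any
7	119303221	120253311	pathref_7_4	any
7	127256881	127680004	pathref_7_5	any
8	552628	1169817	pathref_8_1	any
8	2169515	3900012	pathref_8_2	any
8	13267833	13851792	pathref_8_3	any
8	75783076	76244219	pathref_8_4	any
8	136610079	138721817	pathref_8_5	any
9	22180561	22998892	pathref_9_1	any
9	116304917	117380538	pathref_9_2	any
9	125412423	125957085	pathref_9_3	any
10	34660527	35338422	pathref_10_1	any
10	128128652	128607833	pathref_10_2	any
12	33742329	34542722	pathref_12_1	any
12	130569092	131140277	pathref_12_2	any
15	33135710	33556098	pathref_15_1	any
16	5932658	7010800	pathref_16_1	any
17	162682	587890	pathref_17_1	any
17	823789	1526480	pathref_17_2	any
17	78941152	79515624	pathref_17_3	any
17	79609225	80188991	pathref_17_4	any
18	533160	2250220	pathref_18_1	any
18	7069984	7573165	pathref_18_2	any
19	55227233	59107842	pathref_19_1	any
20	58012338	59017873	pathref_20_1	any
22	16045170	17340096	pathref_22_1	any
X	6445150	8155721	pathref_X_1	any
X	57374046	58448177	pathref_X_2	any
X	67433165	67910951	pathref_X_3	any
X	96695628	98014847	pathref_X_4	any
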