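7	116300000	116500000	hs_7q31.2_MET	any
7	145000000	146000000	hs_7q35_CNTNAP2	any
15	23600000	28800000	hs_15q11-13	any
15	32400000	32900000	hs_15q13.3_CHRNA7	any
16	29500000	30200000	hs_16p11.2	any
22	18600000	23000000	hs_22q11.2	any
22	49300000	51304566	hs_22q13.3_SHANK3	any
X	5800000	6700000	hs_Xp22.3_NLGN4X	any
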