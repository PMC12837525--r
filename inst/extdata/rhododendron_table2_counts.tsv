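species	I	S	T	n_families	filtered_length	filtered_I	filtered_S	filtered_T	n_high
R_prattii	2656	21281	2523	401	805000	2474	19238	2308	202
R_henanense	2770	15452	1490	407	1995000	2750	15337	1480	198
R_griersonianum	3775	28673	3487	454	1455000	3714	27950	3403	216
R_molle	3239	25954	3751	561	335000	3230	25930	3748	267
R_simsii	2096	10360	1878	389	900000	1880	9067	1593	172
R_ovatum	2394	8806	1565	474	0	2394	8806	1565	232
R_ripense	2208	8236	1438	378	2245000	2071	7815	1354	149
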