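slice	lo_kda	hi_kda
1	5	20
2	20	28
3	28	32.2
4	32.2	42
5	42	54.5
6	54.5	65
7	65	85
8	85	110
9	110	165
10	165	300
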