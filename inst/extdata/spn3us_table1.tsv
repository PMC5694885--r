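gp	slice	mass_kda	proc_mass_kda	total_sc
gp75	7	83.9	70.4	1592
gp53	3	45.2	31.5	662
gp54	3	45.1	31.9	643
gp160	1	18.5	NA	175
gp141	4	32.6	NA	306
gp256	7	75.7	NA	669
gp255	4	32.7	NA	209
gp243	6	54.6	NA	251
gp143	3	31.9	NA	118
gp45	5	50.3	48.2	144
gp47	5	62.8	50.7	110
gp50	2	39.4	25.6	56
gp169	9	149	NA	210
gp241	9	159.1	NA	189
gp168	10	188.1	NA	203
gp218	2	25.2	NA	27
gp42	5	49.3	NA	52
gp170	9	135.4	NA	135
gp245	2	30.7	23.4	25
gp81	7	100.2	72.3	93
gp240	6	59.6	NA	33
gp244	2	27	NA	12
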