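protein_id
gp41
gp42
gp45
gp47
gp49
gp50
gp53
gp54
gp75
gp81
gp98
gp141
gp143
gp160
gp168
gp169
gp170
gp218
gp239
gp240
gp241
gp243
gp244
gp245
gp255
gp256
gp100
gp122
gp158
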