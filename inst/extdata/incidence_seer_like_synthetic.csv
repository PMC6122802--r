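age_start,age_end,incidence_per_100k,mortality_per_100k
25,30,10,50
30,35,26,60
35,40,60,80
40,45,122,110
45,50,190,170
50,55,228,280
55,60,268,430
60,65,330,650
65,70,390,1000
70,75,420,1600
75,80,440,2600
80,85,430,4500
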