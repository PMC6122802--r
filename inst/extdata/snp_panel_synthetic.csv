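"rsid","risk_allele","risk_allele_freq","odds_ratio"
"rs2294335","A",0.771,1.077
"rs7150948","C",0.705,1.09
"rs7040382","G",0.793,1.045
"rs5918336","T",0.138,1.071
"rs6540464","A",0.939,1.124
"rs2809994","C",0.923,1.054
"rs4666504","G",0.352,1.08
"rs2755144","A",0.799,1.033
"rs4548112","A",0.117,1.117
"rs2994577","T",0.771,1.097
"rs3336474","C",0.091,1.137
"rs7787944","T",0.473,1.038
"rs7724550","T",0.414,1.097
"rs7223421","A",0.905,1.044
"rs4329451","A",0.259,1.048
"rs4829887","C",0.121,1.06
"rs8593463","T",0.942,1.209
"rs4284182","T",0.282,1.025
"rs8154293","T",0.79,1.093
"rs6709076","T",0.756,1.068
"rs4783745","T",0.84,1.122
"rs8128517","A",0.417,1.142
"rs8255581","T",0.595,1.112
"rs3423982","C",0.393,1.044
"rs7187112","C",0.777,1.022
"rs8636186","C",0.81,1.116
"rs5214096","A",0.587,1.109
"rs2745104","T",0.938,1.077
"rs2212172","C",0.206,1.183
"rs4820522","C",0.175,1.081
"rs3909386","C",0.284,1.063
"rs3812777","A",0.61,1.131
"rs8307874","T",0.42,1.114
"rs6581304","C",0.692,1.113
"rs7405500","G",0.071,1.069
"rs3558794","C",0.175,1.035
"rs3729224","A",0.097,1.084
"rs8961361","A",0.317,1.07
"rs8085804","T",0.814,1.027
"rs3034519","G",0.602,1.053
"rs3370664","G",0.77,1.07
"rs6935099","T",0.203,1.04
"rs8568060","G",0.721,1.037
"rs3269820","T",0.178,1.199
"rs2851085","C",0.5,1.028
"rs5803299","A",0.262,1.049
"rs5891948","A",0.614,1.079
"rs7590063","T",0.148,1.043
"rs3277792","T",0.28,1.04
"rs8483771","A",0.886,1.112
"rs6869209","C",0.262,1.032
"rs7189144","T",0.517,1.117
"rs4593718","G",0.419,1.063
"rs8526921","A",0.622,1.311
"rs6114810","G",0.424,1.154
"rs2226805","C",0.632,1.063
"rs6933684","C",0.714,1.072
"rs7484037","G",0.887,1.148
"rs8599658","A",0.489,1.186
"rs7867498","G",0.348,1.024
"rs2579606","A",0.395,1.04
"rs8788166","T",0.726,1.023
"rs7765428","C",0.136,1.054
"rs8167543","A",0.227,1.047
"rs4757222","A",0.797,1.048
"rs4775406","T",0.722,1.034
"rs4407221","C",0.356,1.09
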