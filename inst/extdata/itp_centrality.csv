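gene_symbol,degree,betweenness,is_hub,is_bottleneck
APOA1,31,0.36595308,TRUE,TRUE
TF,23,0.40234675,TRUE,TRUE
GC,19,0.16563324,TRUE,TRUE
HP,17,0.13375361,TRUE,TRUE
FGG,17,0.11910425,TRUE,FALSE
FGB,15,0.06095966,TRUE,FALSE
FGA,14,0.05532558,TRUE,FALSE
APOB,14,0.02554443,TRUE,FALSE
CDC20,4,0.59090909,FALSE,TRUE
FBXO5,4,0.45454545,FALSE,TRUE
NUP107,5,0.43181818,FALSE,TRUE
SEH1L,5,0.18939394,FALSE,TRUE
TUBB3,2,0.13796193,FALSE,TRUE
KRT1,11,0.1318414,FALSE,TRUE
ARHGEF7,2,0.11959686,FALSE,TRUE
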