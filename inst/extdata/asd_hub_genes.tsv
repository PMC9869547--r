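gene	degree
TP53	333
TNF	253
MAPK3	248
ACTB	213
TLR7	158
LCK	155
RAC2	148
EEF2	148
CAT	137
ZAP70	136
CD19	134
RPLP0	129
CDKN1A	127
CCL2	127
CDK4	124
CCL5	123
CTSD	122
CD4	118
RACK1	117
CD74	117
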