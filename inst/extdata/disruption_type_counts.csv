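EventType,InCascadeCount,DisruptionCount
TRN,117,376
COM,64,278
ENV,4,18
SDM,32,148
IC,26,126
EQ,90,460
PF,11,58
COO,71,385
EXT,13,125
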