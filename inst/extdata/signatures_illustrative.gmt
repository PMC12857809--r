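Th2_illustrative	synthetic illustrative list, not a curated signature	GATA3	IL4	IL5	IL13	IL1RL1
Th1_illustrative	synthetic illustrative list, not a curated signature	TBX21	IFNG	CXCR3	IL12RB2
M2_macrophage_illustrative	synthetic illustrative list, not a curated signature	MRC1	CD163	CCL13	CCL18	VEGFA
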