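roi_id,cell_id,x,y,cell_type
fix,c1,22.1,55.4,EPI
fix,c2,80.6,75.5,EPI
fix,c3,50.9,68.6,EPI
fix,c4,67.4,82.1,IMM
fix,c5,53.1,113.4,IMM
fix,c6,112.0,4.1,IMM
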