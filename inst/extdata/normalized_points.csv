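variant,p,y
P186Q,1,1.00
P186Q,0.8,0.40
P186Q,0.5,0.05
P186Q,0,0.00
R82W,1,1.00
R82W,0.8,0.40
R82W,0.5,0.20
R82W,0,0.00
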