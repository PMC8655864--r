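batch_id,oocyte_id,wt_fraction,rna_ng_total,solution,holding_mV,current_uA
b01,o001,1,2,low_k,-50,-0.1
b01,o001,1,2,high_k,-50,-5.1
b01,o001,1,2,ba,-50,-0.1
b01,o002,0.8,2,low_k,-50,-0.1
b01,o002,0.8,2,high_k,-50,-2.1
b01,o002,0.8,2,ba,-50,-0.1
b01,o003,0.5,2,low_k,-50,-0.1
b01,o003,0.5,2,high_k,-50,-0.35
b01,o003,0.5,2,ba,-50,-0.1
b01,o004,0,2,low_k,-50,-0.1
b01,o004,0,2,high_k,-50,-0.1
b01,o004,0,2,ba,-50,-0.1
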