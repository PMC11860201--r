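shape,wl_low,wl_high,hl_low,hl_high
fragment,0.1,1,0.1,1
sphere,1,1,1,1
fiber,0.01,0.35,0.01,0.35
film,0.1,1,0.001,0.01
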