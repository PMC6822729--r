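,b01,b02,b03,b04,b05,b06,b07,b08,b09,b10,b11,b12,b13,b14,b15,b16,b17
b01,0,0,0,1,1,0,1,0,1,0,0,1,0,0,1,1,0
b02,1,0,0,1,0,0,1,0,1,1,0,1,1,1,0,0,0
b03,0,0,0,1,0,1,0,0,0,0,0,0,0,1,0,0,0
b04,0,1,0,0,1,1,0,0,0,0,0,0,1,1,1,0,0
b05,1,0,1,0,0,0,1,0,1,1,0,1,0,1,1,1,1
b06,0,0,0,0,0,0,1,0,0,0,1,0,0,0,1,0,0
b07,0,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0
b08,0,1,1,1,0,1,1,0,1,1,1,1,0,0,0,0,1
b09,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
b10,0,0,0,0,0,0,1,1,1,0,0,0,0,1,0,1,1
b11,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
b12,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
b13,1,1,0,0,0,1,1,0,0,0,0,1,0,1,1,1,1
b14,0,1,1,0,1,0,0,1,0,0,0,0,0,0,0,0,0
b15,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0
b16,0,1,1,1,1,1,0,1,0,1,1,0,0,1,1,0,1
b17,1,0,1,1,0,0,1,1,1,0,0,0,0,1,1,1,0
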