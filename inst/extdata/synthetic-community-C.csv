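,c01,c02,c03,c04,c05,c06,c07,c08,c09,c10,c11,c12,c13,c14,c15,c16,c17
c01,0,0,0,1,0,1,0,1,1,1,0,0,1,0,0,0,0
c02,0,0,0,1,1,0,0,1,0,0,0,1,0,0,0,1,0
c03,1,0,0,0,0,0,1,1,1,1,0,0,0,0,0,0,0
c04,1,0,1,0,0,0,0,1,0,1,0,0,0,1,0,0,0
c05,0,0,0,1,0,1,1,0,0,0,0,0,0,0,0,1,1
c06,1,0,0,0,1,0,0,1,0,1,0,0,0,0,1,0,0
c07,0,1,0,0,0,0,0,1,0,1,0,0,1,1,0,1,0
c08,0,0,0,0,0,0,1,0,0,1,1,0,0,0,0,1,1
c09,0,0,0,1,1,0,0,1,0,1,0,0,0,0,0,1,0
c10,0,0,0,0,1,1,0,0,0,0,1,0,0,1,0,1,0
c11,1,0,0,0,0,0,1,0,1,0,0,1,0,0,1,0,1
c12,0,1,0,0,0,0,1,0,1,1,0,0,1,0,0,0,0
c13,1,0,0,0,1,1,0,0,0,0,0,1,0,0,0,0,0
c14,0,0,0,1,0,0,1,1,0,0,0,0,0,0,0,0,1
c15,0,0,0,1,0,0,1,0,0,0,0,0,0,1,0,0,0
c16,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,1
c17,0,0,1,0,1,0,0,0,0,1,0,0,1,0,0,0,0
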