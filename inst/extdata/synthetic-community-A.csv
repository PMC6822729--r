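,a01,a02,a03,a04,a05,a06,a07,a08,a09,a10,a11,a12,a13,a14,a15,a16,a17,a18
a01,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0
a02,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,1
a03,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
a04,0,0,0,0,0,1,0,0,0,1,0,0,1,0,1,0,0,0
a05,0,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0
a06,0,1,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,1
a07,0,0,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0
a08,1,1,0,1,1,1,1,0,1,1,1,1,1,1,1,1,1,1
a09,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1
a10,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
a11,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
a12,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
a13,0,1,0,0,1,0,0,0,1,0,0,0,0,1,0,0,0,0
a14,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1
a15,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
a16,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0
a17,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0
a18,0,1,1,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0
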