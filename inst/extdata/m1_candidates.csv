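"","T1","T2","T3"
"T1",0,1,0
"T2",1,0,1
"T3",0,1,0
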