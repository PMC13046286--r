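"node","family","trials"
"T1","gaussian",NA
"T2","gaussian",NA
"T3","gaussian",NA
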