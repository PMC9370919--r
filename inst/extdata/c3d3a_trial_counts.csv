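subject,left,right,foot,tongue
1,45,45,45,45
2,30,30,30,30
3,30,30,30,30
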