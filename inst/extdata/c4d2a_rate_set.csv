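set,run,success_rate
1,1,0.966435
1,2,0.976852
1,3,0.984954
1,4,0.971065
1,5,0.969136
1,6,0.983025
1,7,0.986883
1,8,0.985725
1,9,0.984182
1,10,0.978395
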