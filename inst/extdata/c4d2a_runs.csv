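run,failed_1,failed_2,failed_3,failed_4,failed_5,failed_6,failed_7,failed_8,failed_9,total,success_rate
1,18,6,19,9,7,6,2,13,7,288,0.966435
2,7,9,3,5,4,8,6,6,12,288,0.976852
3,2,2,10,1,6,5,0,4,9,288,0.984954
4,19,8,10,7,1,9,7,8,6,288,0.971065
5,11,5,10,13,10,12,5,10,4,288,0.969136
6,6,4,7,5,3,2,2,8,7,288,0.983025
7,3,5,3,1,3,7,4,6,2,288,0.986883
8,3,4,5,0,3,4,7,5,6,288,0.985725
9,1,8,9,3,3,4,0,9,4,288,0.984182
10,12,7,9,4,4,5,2,7,6,288,0.978395
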