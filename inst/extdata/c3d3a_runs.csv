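run,failed_1,total_1,failed_2,total_2,failed_3,total_3,success_rate
1,26,180,15,120,19,120,0.857143
2,16,180,10,120,3,120,0.930952
3,11,180,13,120,6,120,0.928571
4,9,180,17,120,5,120,0.926190
5,5,180,12,120,6,120,0.945238
6,30,180,14,120,13,120,0.864286
7,27,180,9,120,18,120,0.871429
8,42,180,32,120,17,120,0.783333
9,10,180,15,120,5,120,0.928571
10,18,180,0,120,2,120,0.952381
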