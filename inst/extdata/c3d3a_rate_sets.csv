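set,run,success_rate
1,1,0.907143
1,2,0.795238
1,3,0.802381
1,4,0.980952
1,5,0.919048
1,6,0.859524
1,7,0.921429
1,8,0.904762
1,9,0.909524
1,10,0.821429
2,1,0.857143
2,2,0.930952
2,3,0.928571
2,4,0.926190
2,5,0.945238
2,6,0.864286
2,7,0.871429
2,8,0.783333
2,9,0.928571
2,10,0.952381
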