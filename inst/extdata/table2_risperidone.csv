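from,1,2,3,4,5,6,7,8,n
1,100.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,2
2,3.31,80.99,0.00,9.09,5.79,0.83,0.00,0.00,121
3,0.00,0.00,100.00,0.00,0.00,0.00,0.00,0.00,2
4,0.00,22.10,0.55,74.31,0.83,2.21,0.00,0.00,362
5,0.00,16.07,0.00,3.57,75.00,5.36,0.00,0.00,56
6,0.00,2.87,0.00,8.91,12.07,76.15,0.00,0.00,348
7,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0
8,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0
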