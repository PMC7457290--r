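from,1,2,3,4,5,6,7,8,n
1,100.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,3
2,6.03,87.07,0.00,5.17,1.72,0.00,0.00,0.00,116
3,0.00,100.00,0.00,0.00,0.00,0.00,0.00,0.00,1
4,0.00,19.89,0.27,75.33,0.53,3.98,0.00,0.00,377
5,0.00,22.92,0.00,0.00,70.83,6.25,0.00,0.00,48
6,0.00,3.51,0.00,11.99,10.53,73.98,0.00,0.00,342
7,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0
8,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0
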