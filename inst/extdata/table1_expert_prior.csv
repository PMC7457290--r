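from,1,2,3,4,5,6,7,8
1,82.39,5.42,4.81,2.00,1.56,1.40,1.54,0.88
2,8.12,49.90,14.46,12.49,5.05,3.73,3.17,3.07
3,3.96,19.54,42.86,16.14,6.29,3.78,5.27,2.16
4,3.65,10.65,6.07,52.76,9.59,10.34,3.90,3.05
5,2.03,3.73,5.09,5.03,58.51,16.05,6.61,2.96
6,1.99,3.00,5.03,5.48,16.97,54.31,8.39,4.83
7,1.50,2.38,4.87,3.48,23.14,13.28,45.90,5.46
8,2.26,2.46,4.49,7.06,9.63,20.61,7.43,46.06
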