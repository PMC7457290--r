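arm,prior,from,1,2,3,4,5,6,7,8
risperidone,informative,1,94.11,1.80,1.60,0.68,0.55,0.47,0.51,0.28
risperidone,informative,2,3.35,80.72,0.12,9.13,5.78,0.85,0.03,0.03
risperidone,informative,3,1.33,6.60,80.97,5.23,2.09,1.31,1.76,0.71
risperidone,informative,4,0.01,22.07,0.57,74.24,0.85,2.23,0.01,0.01
risperidone,informative,5,0.03,15.83,0.09,3.61,74.71,5.56,0.11,0.05
risperidone,informative,6,0.01,2.88,0.01,8.90,12.08,76.09,0.02,0.01
risperidone,informative,7,1.49,2.37,4.98,3.46,23.01,13.25,45.98,5.46
risperidone,informative,8,2.22,2.51,4.51,7.04,9.62,20.56,7.41,46.15
risperidone,vague,1,70.98,4.15,4.16,4.10,4.16,4.14,4.18,4.13
risperidone,vague,2,3.39,80.43,0.10,9.13,5.83,0.93,0.11,0.10
risperidone,vague,3,4.13,4.16,70.92,4.18,4.10,4.19,4.20,4.12
risperidone,vague,4,0.03,22.07,0.59,74.13,0.86,2.24,0.03,0.03
risperidone,vague,5,0.21,16.01,0.21,3.74,73.89,5.49,0.22,0.22
risperidone,vague,6,0.04,2.89,0.04,8.92,12.07,75.97,0.04,0.04
risperidone,vague,7,12.41,12.51,12.51,12.55,12.51,12.71,12.45,12.34
risperidone,vague,8,12.44,12.44,12.49,12.46,12.64,12.52,12.42,12.59
cariprazine,informative,1,95.55,1.40,1.23,0.51,0.39,0.34,0.36,0.22
cariprazine,informative,2,6.05,86.77,0.12,5.23,1.74,0.03,0.03,0.03
cariprazine,informative,3,1.98,59.77,21.44,8.02,3.08,1.92,2.69,1.12
cariprazine,informative,4,0.01,19.86,0.28,75.28,0.55,3.99,0.01,0.01
cariprazine,informative,5,0.04,22.52,0.11,0.10,70.55,6.48,0.13,0.06
cariprazine,informative,6,0.01,3.51,0.02,11.97,10.55,73.92,0.02,0.01
cariprazine,informative,7,1.58,2.45,4.83,3.50,23.12,13.31,45.80,5.41
cariprazine,informative,8,2.37,2.48,4.47,7.18,9.60,20.59,7.42,45.90
cariprazine,vague,1,77.95,3.15,3.13,3.12,3.18,3.20,3.11,3.16
cariprazine,vague,2,6.09,86.42,0.11,5.24,1.83,0.11,0.11,0.11
cariprazine,vague,3,6.30,56.30,6.29,6.26,6.26,6.09,6.29,6.27
cariprazine,vague,4,0.03,19.87,0.30,75.16,0.56,4.01,0.03,0.03
cariprazine,vague,5,0.25,22.69,0.25,0.25,69.65,6.38,0.26,0.25
cariprazine,vague,6,0.04,3.59,0.04,12.00,10.54,73.78,0.04,0.04
cariprazine,vague,7,12.53,12.56,12.47,12.44,12.42,12.49,12.45,12.64
cariprazine,vague,8,12.42,12.31,12.67,12.52,12.39,12.56,12.56,12.56
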