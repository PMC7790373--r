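layer1,layer2,five_fold,lobo,tb
6,6,1,0.976,1
6,12,0.999,1,1
6,24,0.999,1,1
6,36,0.892,0.8,1
6,48,1,1,1
6,60,0.911,0.823,0.907
12,6,0.938,1,1
12,12,0.774,0.897,1
12,24,0.764,0.731,0.987
12,36,0.876,0.785,0.908
12,48,0.926,0.988,0.843
12,60,0.766,0.719,0.868
24,6,0.797,0.755,0.955
24,12,0.861,0.866,0.904
24,24,0.754,0.78,0.997
24,36,0.812,0.783,0.924
24,48,0.697,0.811,0.86
24,60,0.847,0.787,0.782
36,6,0.786,0.856,0.705
36,12,0.833,0.8,0.915
36,24,0.749,0.656,0.898
36,36,0.88,0.808,0.874
36,48,0.825,0.805,1
36,60,0.871,0.824,1
48,6,0.785,0.882,0.995
48,12,0.788,0.717,0.875
48,24,0.783,0.765,0.98
48,36,0.778,0.769,0.904
48,48,0.807,0.758,0.992
48,60,0.854,0.813,0.954
60,6,0.848,0.801,0.89
60,12,0.752,0.676,0.806
60,24,0.83,0.845,0.929
60,36,0.81,0.773,0.84
60,48,0.756,0.732,0.898
60,60,0.755,0.73,0.944
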