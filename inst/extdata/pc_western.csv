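age_index,age_midpoint,pop_rate_per_100k,pop_se_per_100k,ind_rate_per_100k,ind_se_per_100k
1,32.5,6.41E-02,7.22E-03,2.52E+01,2.84E+00
2,37.5,1.39E-01,1.11E-02,5.49E+01,4.38E+00
3,42.5,3.72E-01,1.92E-02,1.47E+02,7.59E+00
4,47.5,8.70E-01,3.15E-02,3.49E+02,1.26E+01
5,52.5,1.68E+00,4.68E-02,6.90E+02,1.93E+01
6,57.5,2.85E+00,6.61E-02,1.23E+03,2.87E+01
7,62.5,4.28E+00,8.77E-02,2.00E+03,4.14E+01
8,67.5,6.11E+00,1.12E-01,3.26E+03,6.11E+01
9,72.5,7.29E+00,1.35E-01,4.73E+03,9.13E+01
10,77.5,7.74E+00,1.58E-01,6.63E+03,1.47E+02
11,82.5,7.17E+00,1.87E-01,9.03E+03,2.70E+02
12,87.5,6.13E+00,2.36E-01,1.33E+04,6.65E+02
13,92.5,3.91E+00,2.99E-01,1.86E+04,2.19E+03
14,97.5,2.24E+00,4.47E-01,4.00E+04,2.15E+04
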