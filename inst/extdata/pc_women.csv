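age_index,age_midpoint,pop_rate_per_100k,pop_se_per_100k,ind_rate_per_100k,ind_se_per_100k
1,32.5,5.70E-02,6.52E-03,2.35E+01,2.69E+00
2,37.5,1.41E-01,1.06E-02,5.81E+01,4.37E+00
3,42.5,3.04E-01,1.63E-02,1.26E+02,6.75E+00
4,47.5,7.20E-01,2.67E-02,3.02E+02,1.12E+01
5,52.5,1.36E+00,3.90E-02,5.85E+02,1.67E+01
6,57.5,2.44E+00,5.57E-02,1.09E+03,2.50E+01
7,62.5,3.58E+00,7.21E-02,1.72E+03,3.47E+01
8,67.5,5.45E+00,9.36E-02,2.93E+03,5.12E+01
9,72.5,6.89E+00,1.13E-01,4.44E+03,7.55E+01
10,77.5,7.71E+00,1.32E-01,6.50E+03,1.20E+02
11,82.5,7.20E+00,1.50E-01,8.84E+03,2.11E+02
12,87.5,5.98E+00,1.77E-01,1.23E+04,4.61E+02
13,92.5,4.17E+00,2.26E-01,1.80E+04,1.47E+03
14,97.5,2.54E+00,3.37E-01,4.00E+04,1.43E+04
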