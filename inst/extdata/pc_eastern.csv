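age_index,age_midpoint,pop_rate_per_100k,pop_se_per_100k,ind_rate_per_100k,ind_se_per_100k
1,32.5,6.52E-02,6.67E-03,2.34E+01,2.39E+00
2,37.5,2.07E-01,1.22E-02,7.44E+01,4.40E+00
3,42.5,4.29E-01,1.84E-02,1.55E+02,6.66E+00
4,47.5,9.61E-01,2.93E-02,3.52E+02,1.07E+01
5,52.5,1.88E+00,4.34E-02,7.07E+02,1.63E+01
6,57.5,3.18E+00,6.03E-02,1.26E+03,2.39E+01
7,62.5,4.66E+00,7.84E-02,1.99E+03,3.38E+01
8,67.5,6.54E+00,9.98E-02,3.18E+03,4.94E+01
9,72.5,8.11E+00,1.22E-01,4.79E+03,7.50E+01
10,77.5,8.71E+00,1.42E-01,6.85E+03,1.22E+02
11,82.5,8.18E+00,1.68E-01,9.63E+03,2.31E+02
12,87.5,6.36E+00,1.97E-01,1.31E+04,5.23E+02
13,92.5,4.31E+00,2.56E-01,1.97E+04,1.85E+03
14,97.5,2.22E+00,3.59E-01,4.00E+04,1.74E+04
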