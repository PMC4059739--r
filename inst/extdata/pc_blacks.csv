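age_index,age_midpoint,pop_rate_per_100k,pop_se_per_100k,ind_rate_per_100k,ind_se_per_100k
1,32.5,7.31E-02,1.46E-02,1.97E+01,3.94E+00
2,37.5,2.83E-01,3.06E-02,7.65E+01,8.26E+00
3,42.5,6.04E-01,4.81E-02,1.64E+02,1.31E+01
4,47.5,1.46E+00,8.24E-02,4.01E+02,2.27E+01
5,52.5,2.85E+00,1.27E-01,8.08E+02,3.62E+01
6,57.5,4.79E+00,1.84E-01,1.44E+03,5.55E+01
7,62.5,6.88E+00,2.44E-01,2.26E+03,8.10E+01
8,67.5,9.00E+00,3.04E-01,3.41E+03,1.18E+02
9,72.5,1.06E+01,3.82E-01,4.92E+03,1.86E+02
10,77.5,1.02E+01,4.41E-01,6.27E+03,2.90E+02
11,82.5,1.05E+01,5.86E-01,9.45E+03,6.12E+02
12,87.5,8.04E+00,7.16E-01,1.24E+04,1.40E+03
13,92.5,4.75E+00,8.58E-01,1.44E+04,3.51E+03
14,97.5,4.21E+00,1.44E+00,4.00E+04,3.70E+04
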