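age_index,age_midpoint,pop_rate_per_100k,pop_se_per_100k,ind_rate_per_100k,ind_se_per_100k
1,32.5,7.14E-02,7.26E-03,2.32E+01,2.37E+00
2,37.5,2.13E-01,1.30E-02,6.95E+01,4.25E+00
3,42.5,5.23E-01,2.15E-02,1.72E+02,7.06E+00
4,47.5,1.13E+00,3.39E-02,3.77E+02,1.13E+01
5,52.5,2.24E+00,5.09E-02,7.68E+02,1.75E+01
6,57.5,3.68E+00,7.05E-02,1.33E+03,2.55E+01
7,62.5,5.52E+00,9.40E-02,2.17E+03,3.73E+01
8,67.5,7.46E+00,1.20E-01,3.37E+03,5.53E+01
9,72.5,8.95E+00,1.48E-01,4.96E+03,8.59E+01
10,77.5,9.29E+00,1.78E-01,6.88E+03,1.43E+02
11,82.5,8.79E+00,2.23E-01,9.79E+03,2.91E+02
12,87.5,6.89E+00,2.86E-01,1.36E+04,7.42E+02
13,92.5,4.35E+00,3.94E-01,1.94E+04,2.75E+03
14,97.5,2.32E+00,6.19E-01,4.00E+04,2.87E+04
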