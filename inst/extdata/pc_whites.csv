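age_index,age_midpoint,pop_rate_per_100k,pop_se_per_100k,ind_rate_per_100k,ind_se_per_100k
1,32.5,6.22E-02,5.14E-03,2.37E+01,1.96E+00
2,37.5,1.62E-01,8.55E-03,6.17E+01,3.26E+00
3,42.5,3.88E-01,1.39E-02,1.49E+02,5.32E+00
4,47.5,8.60E-01,2.20E-02,3.34E+02,8.53E+00
5,52.5,1.67E+00,3.25E-02,6.67E+02,1.29E+01
6,57.5,2.86E+00,4.54E-02,1.19E+03,1.90E+01
7,62.5,4.28E+00,5.97E-02,1.93E+03,2.71E+01
8,67.5,6.13E+00,7.66E-02,3.13E+03,3.98E+01
9,72.5,7.56E+00,9.29E-02,4.67E+03,5.98E+01
10,77.5,8.21E+00,1.09E-01,6.71E+03,9.69E+01
11,82.5,7.60E+00,1.28E-01,9.17E+03,1.78E+02
12,87.5,6.14E+00,1.54E-01,1.27E+04,4.04E+02
13,92.5,4.17E+00,2.01E-01,1.83E+04,1.35E+03
14,97.5,2.46E+00,3.05E-01,4.00E+04,1.33E+04
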