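stratum,apm_zip_days,apm_person_days_m,apm_pct,rx_zip_days,rx_person_days_m,rx_pct,wf_zip_days,wf_person_days_m,wf_pct,frx_zip_days,frx_person_days_m,frx_pct
0.01-0.05,9,0.1,0.001,14792,398.8,56.7,78439,2324.5,37.2,83875,2387.9,22.8
0.06-0.10,17,0.3,0.002,3300,87.8,12.5,22709,663.5,10.6,47099,1341.2,12.8
0.11-0.25,88,0.9,0.007,3548,91.9,13.1,29831,863.6,13.8,83584,2381.4,22.7
0.26-0.50,520,5.0,0.04,2015,49.4,7.0,21124,607.3,9.7,65366,1875.8,17.9
0.51-1.00,3000,30.4,0.2,1440,33.3,4.7,19466,553.9,8.9,48972,1400.6,13.4
1.01-5.00,119525,2353.9,17.6,1610,34.8,5.0,31642,866.9,13.9,37621,1026.2,9.8
5.01-10.00,194353,5691.1,42.5,236,4.4,0.6,7135,185.2,3.0,1975,47.2,0.5
10.01-15.00,100017,3396.7,25.4,66,1.3,0.2,2723,67.9,1.1,387,9.3,0.1
15.01-20.00,30950,1070.7,8.0,24,0.4,0.1,1364,33.0,0.5,132,3.3,0.03
20.01-50.00,23849,802.4,6.0,36,0.5,0.1,2341,53.6,0.9,114,2.7,0.03
50.01-1120.00,1376,41.0,0.3,24,0.6,0.1,1159,21.5,0.3,5,0.1,0.001
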