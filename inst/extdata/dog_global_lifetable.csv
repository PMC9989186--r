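age_interval,P,d,m,q,l,L,T,e,ci_low,ci_high
0-1,1608758,43476,0.0270,0.0267,100000,97867,1269213,12.69,12.68,12.70
1-2,1331906,14276,0.0107,0.0107,97334,96815,1171346,12.03,12.03,12.04
2-3,1177583,11310,0.0096,0.0096,96296,95836,1074532,11.16,11.15,11.17
3-4,1093330,11480,0.0105,0.0104,95375,94877,978696,10.26,10.25,10.27
4-5,1066987,13148,0.0123,0.0122,94379,93801,883819,9.36,9.36,9.37
5-6,1008031,16145,0.0160,0.0159,93223,92483,790017,8.47,8.47,8.48
6-7,935213,19637,0.0210,0.0208,91742,90789,697535,7.60,7.60,7.61
7-8,887776,26388,0.0297,0.0293,89836,88520,606746,6.75,6.75,6.76
8-9,810013,35663,0.0440,0.0431,87205,85326,518225,5.94,5.93,5.95
9-10,707952,45257,0.0639,0.0619,83448,80863,432899,5.19,5.18,5.20
10-11,614524,56118,0.0913,0.0873,78279,74860,352036,4.50,4.49,4.50
11-12,484797,60550,0.1249,0.1176,71442,67243,277175,3.88,3.87,3.89
12-13,371564,64343,0.1732,0.1594,63044,58020,209932,3.33,3.32,3.34
13-14,265424,61806,0.2329,0.2086,52997,47470,151912,2.87,2.86,2.88
14-15,168706,51430,0.3048,0.2645,41943,36395,104442,2.49,2.48,2.50
15-16,92503,35442,0.3831,0.3215,30848,25888,68047,2.21,2.19,2.22
16-17,42472,19224,0.4526,0.3691,20929,17066,42159,2.01,2.00,2.03
17+,26010,13687,0.5262,0.4166,13204,25092,25092,1.90,1.88,1.92
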