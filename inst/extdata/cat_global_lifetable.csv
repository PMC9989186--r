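age_interval,P,d,m,q,l,L,T,e,ci_low,ci_high
0-1,325096,17200,0.0529,0.0515,100000,95876,1118000,11.18,11.16,11.20
1-2,231549,7321,0.0316,0.0311,94846,93370,1022123,10.78,10.75,10.80
2-3,185553,5467,0.0295,0.0290,91893,90559,928754,10.11,10.09,10.13
3-4,162631,4877,0.0300,0.0295,89225,87907,838194,9.39,9.37,9.42
4-5,150407,4827,0.0321,0.0316,86589,85222,750287,8.66,8.64,8.69
5-6,138833,5423,0.0391,0.0383,83854,82248,665066,7.93,7.91,7.95
6-7,125243,5401,0.0431,0.0422,80641,78939,582818,7.23,7.21,7.25
7-8,118952,6291,0.0529,0.0515,77237,75247,503878,6.52,6.51,6.54
8-9,112659,7735,0.0687,0.0664,73258,70826,428631,5.85,5.83,5.87
9-10,100971,8041,0.0796,0.0766,68395,65776,357805,5.23,5.22,5.25
10-11,99722,11352,0.1138,0.1077,63157,59755,292029,4.62,4.61,4.64
11-12,84860,10704,0.1261,0.1187,56354,53011,232277,4.12,4.11,4.14
12-13,79909,13446,0.1683,0.1552,49668,45813,179263,3.61,3.60,3.62
13-14,70670,14571,0.2062,0.1869,41959,38037,133449,3.18,3.17,3.19
14-15,60980,15636,0.2564,0.2273,34116,30239,95412,2.80,2.78,2.81
15-16,50674,15945,0.3147,0.2719,26362,22779,65173,2.47,2.46,2.49
16-17,37426,13940,0.3725,0.3140,19195,16181,42394,2.21,2.19,2.22
17+,57088,28678,0.5023,0.4015,13168,26213,26213,1.99,1.97,2.01
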