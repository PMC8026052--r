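position	score
1	4.65709509260878
2	-1.30677299070501
3	1.13497100864504
4	1.12700534214021
5	3.33434616142133
6	-0.890516680464772
7	3.10437041941732
8	2.3454752733455
9	4.50133559888196
10	-2.60005536748252
11	3.1649639051922
12	0.0531638057136377
13	1.64261082830816
14	0.242044428552871
15	3.33067181683842
16	2.07734267985738
17	3.3190679535985
18	3.03007369545318
19	2.62425861886502
20	3.19844890926769
21	3.04769877954637
22	-1.92158010137937
23	3.70257259651905
24	3.54219441583009
25	3.58028007806211
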