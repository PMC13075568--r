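node_id	roi_id
1	1
2	1
3	1
4	2
5	2
6	2
7	3
8	3
9	3
10	4
11	4
12	4
13	5
14	5
15	5
16	6
17	6
18	6
19	7
20	7
21	7
22	8
23	8
24	8
25	9
26	9
27	9
28	10
29	10
30	10
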