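chrom	length_mb	spo11_count
1	195.47	7756
2	182.11	6796
3	160.04	5875
4	156.51	7274
5	151.83	5842
6	149.74	6049
7	145.44	5046
8	129.4	4703
9	124.6	4734
10	130.69	4605
11	122.08	4561
12	120.13	5145
13	120.42	3831
14	124.9	4945
15	104.04	4168
16	98.21	4168
17	94.99	4116
18	90.7	4104
19	61.43	2382
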