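n_utrsnp	n_genes
1	3435
2	1438
3	670
4	313
5	138
6	80
7	35
8	17
9	7
10	4
11	5
12	1
13	1
14	2
18	1
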