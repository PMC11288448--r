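# nodes=16
0 1
0 4
1 0
1 2
1 5
2 1
2 3
2 6
3 2
3 7
4 0
4 5
4 8
5 4
5 6
5 9
6 5
6 7
6 10
7 6
7 11
8 4
8 9
8 12
9 5
9 8
9 10
10 6
10 9
10 11
11 7
11 10
12 8
12 13
13 9
13 12
13 14
14 10
14 13
14 15
15 11
15 14
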