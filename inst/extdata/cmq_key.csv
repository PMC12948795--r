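item,option,points
1,1,1
1,2,2
1,3,3
1,4,4
2,1,1
2,2,2
2,3,3
2,4,4
3,1,1
3,2,2
3,3,3
3,4,4
4,1,1
4,2,2
4,3,3
4,4,4
5,1,1
5,2,2
5,3,3
5,4,4
6,1,1
6,2,2
6,3,3
6,4,4
7,1,1
7,2,2
7,3,3
7,4,4
8,1,1
8,2,2
8,3,3
8,4,4
9,1,1
9,2,2
9,3,3
9,4,4
10,1,1
10,2,2
10,3,3
10,4,4
11,1,1
11,2,2
11,3,3
11,4,4
11,5,5
12,1,1
12,2,2
12,3,3
12,4,4
12,5,5
13,1,1
13,2,2
13,3,3
13,4,4
13,5,5
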