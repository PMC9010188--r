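"respondent","artwork","rating"
1,1,80
2,1,80
3,1,80
4,1,80
5,1,80
6,1,80
7,1,80
8,1,80
9,1,80
10,1,80
11,1,80
12,1,80
13,1,80
14,1,80
15,1,84
16,1,84
17,1,84
18,1,84
19,1,84
20,1,84
21,1,84
22,1,84
23,1,84
24,1,84
25,1,84
26,1,84
27,1,84
28,1,84
1,2,76
2,2,76
3,2,76
4,2,76
5,2,76
6,2,76
7,2,76
8,2,76
9,2,76
10,2,76
11,2,76
12,2,76
13,2,76
14,2,76
15,2,80
16,2,80
17,2,80
18,2,80
19,2,80
20,2,80
21,2,80
22,2,80
23,2,80
24,2,80
25,2,80
26,2,80
27,2,80
28,2,80
1,3,73
2,3,73
3,3,73
4,3,73
5,3,73
6,3,73
7,3,73
8,3,73
9,3,73
10,3,73
11,3,73
12,3,73
13,3,73
14,3,73
15,3,77
16,3,77
17,3,77
18,3,77
19,3,77
20,3,77
21,3,77
22,3,77
23,3,77
24,3,77
25,3,77
26,3,77
27,3,77
28,3,77
1,4,71
2,4,71
3,4,71
4,4,71
5,4,71
6,4,71
7,4,71
8,4,71
9,4,71
10,4,71
11,4,71
12,4,71
13,4,71
14,4,71
15,4,75
16,4,75
17,4,75
18,4,75
19,4,75
20,4,75
21,4,75
22,4,75
23,4,75
24,4,75
25,4,75
26,4,75
27,4,75
28,4,75
1,5,68
2,5,68
3,5,68
4,5,68
5,5,68
6,5,68
7,5,68
8,5,68
9,5,68
10,5,68
11,5,68
12,5,68
13,5,68
14,5,68
15,5,72
16,5,72
17,5,72
18,5,72
19,5,72
20,5,72
21,5,72
22,5,72
23,5,72
24,5,72
25,5,72
26,5,72
27,5,72
28,5,72
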