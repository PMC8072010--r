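"item","immediate_amount","delayed_amount","delay_days","magnitude_bin"
1,7,8,175,"small"
2,21,22,173,"medium"
3,37,39,117,"large"
4,11,12,113,"small"
5,21,22,66,"medium"
6,31,34,142,"large"
7,7,8,136,"small"
8,22,23,35,"medium"
9,28,33,95,"large"
10,8,11,177,"small"
11,18,24,104,"medium"
12,33,38,38,"large"
13,5,9,150,"small"
14,17,23,47,"medium"
15,23,30,30,"large"
16,4,9,89,"small"
17,7,21,131,"medium"
18,12,30,71,"large"
19,9,10,5,"small"
20,10,23,33,"medium"
21,5,34,118,"large"
22,1,11,104,"small"
23,8,21,21,"medium"
24,4,31,58,"large"
25,6,11,5,"small"
26,1,21,168,"medium"
27,1,39,133,"large"
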