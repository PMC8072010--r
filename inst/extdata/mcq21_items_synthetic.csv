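"item","immediate_amount","delayed_amount","delay_days","magnitude_bin"
1,33,34,169,"small"
2,51,53,150,"medium"
3,78,81,96,"large"
4,31,32,29,"small"
5,52,57,128,"medium"
6,69,80,131,"large"
7,31,34,50,"small"
8,39,55,170,"medium"
9,78,85,26,"large"
10,20,30,103,"small"
11,49,59,29,"medium"
12,31,85,171,"large"
13,11,26,95,"small"
14,12,54,164,"medium"
15,15,79,151,"large"
16,4,32,147,"small"
17,6,54,125,"medium"
18,5,75,151,"large"
19,4,25,41,"small"
20,3,59,112,"medium"
21,4,79,81,"large"
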