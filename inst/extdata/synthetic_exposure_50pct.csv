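age_start,n,exposure
0,1,80000
1,4,320000
5,5,4e+05
10,5,4e+05
15,5,4e+05
20,5,430000
25,5,450000
30,5,440000
35,5,420000
40,5,4e+05
45,5,390000
50,5,380000
55,5,370000
60,5,340000
65,5,3e+05
70,5,240000
75,5,170000
80,5,110000
85,+,90000
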