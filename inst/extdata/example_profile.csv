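# example CPB temperature profile: cooling, hypothermia maintenance, rewarming
time_min,temp_c
0,36.8
5,35.0
10,32.5
15,30.0
25,28.0
40,28.0
55,28.0
65,30.0
75,32.5
85,35.0
95,36.8
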