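marker_kda
250
180
130
100
70
55
40
35
25
15
10
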