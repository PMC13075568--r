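roi_left	roi_right
1	6
2	7
3	8
4	9
5	10
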