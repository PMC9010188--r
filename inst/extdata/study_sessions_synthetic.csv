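"subject","artwork","baseline","stimulus"
1,1,45,84
2,1,48,85
3,1,44,79
4,1,50,80
5,1,46,83
6,1,47.8,75
1,5,47,72
2,5,49,67
3,5,50,73
4,5,46,71
5,5,48,66
6,5,49.24,72.24
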