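zone,x,y
1,-27,3
1,-21,3
1,-15,3
1,-21,9
1,-15,9
2,-9,3
2,-3,3
2,3,3
2,9,3
2,-9,9
3,-3,9
3,3,9
3,9,9
3,3,15
3,-3,15
4,9,15
4,15,15
4,15,9
4,21,9
4,21,3
5,-9,15
5,-15,15
5,-9,21
5,-3,21
5,3,21
5,9,21
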