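day,tester,estimate_pct,reference_pct
1,1,96,96
1,2,96,96
1,3,97,97
1,4,97,97
1,5,98,98
1,6,97,97
2,1,96,97
2,2,97,97
2,3,97,96
2,4,97,97
2,5,97,98
2,6,97,99
3,1,96,97
3,2,97,97
3,3,96,95
3,4,96,96
3,5,97,97
3,6,97,98
4,1,96,96
4,2,97,97
4,3,97,96
4,4,97,96
4,5,97,97
4,6,96,97
5,1,96,96
5,2,98,97
5,3,96,96
5,4,96,96
5,5,97,98
5,6,97,98
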