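"time_h","flow_ml_min"
0.23,14.289
0.43,8.856
0.79,4.82
0.86,2.923
0.87,4.379
1.62,1.943
1.72,2.149
2.37,1.556
3.19,0.856
3.98,0.748
4.48,0.594
5.46,0.641
6.54,0.38
6.69,0.457
9.34,0.269
9.78,0.293
14.68,0.2
17.45,0.194
17.9,0.131
19.7,0.126
23.22,0.143
37.58,0.065
38.17,0.071
43.73,0.055
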