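"N","lpr"
1,1.06247068875022
2,2.53710377518439
3,3.87385143094517
4,4.56125871723474
5,4.92000324616585
8,5.26328670746321
10,5.62606809859091
16,5.76264279968816
32,5.98447201400524
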