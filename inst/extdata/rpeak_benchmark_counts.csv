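method,file,tp,tn,fp,fn,sensitivity,precision,specificity
custom,001,11780,1188216,2,2,0.999830,0.999830,0.999998
custom,002,12413,1187556,16,15,0.998793,0.998713,0.999987
custom,003,11274,1188723,1,2,0.999823,0.999911,0.999999
custom,004,11209,1188758,18,15,0.998664,0.998397,0.999985
custom,005,10524,1189468,4,4,0.999620,0.999620,0.999997
custom,006,11580,1188405,8,7,0.999396,0.999310,0.999993
custom,007,10794,1189197,2,7,0.999352,0.999815,0.999998
custom,008,11085,1188871,25,19,0.998289,0.997750,0.999979
custom,009,13366,1186524,56,54,0.995976,0.995828,0.999953
custom,010,13411,1186489,45,55,0.995916,0.996656,0.999962
physiozoo,001,11773,1188209,11,9,0.999236,0.999067,0.999991
physiozoo,002,12417,1188484,3,11,0.999115,0.999758,0.999997
physiozoo,003,11270,1187595,6,6,0.999468,0.999468,0.999995
physiozoo,004,11222,1188730,3,2,0.999822,0.999733,0.999997
physiozoo,005,10521,1189491,9,7,0.999335,0.999145,0.999992
physiozoo,006,11574,1188412,7,13,0.998878,0.999396,0.999994
physiozoo,007,10785,1189199,11,16,0.998519,0.998981,0.999991
physiozoo,008,11072,1188864,29,32,0.997118,0.997388,0.999976
physiozoo,009,13348,1186497,73,72,0.994635,0.994561,0.999938
physiozoo,010,13410,1186419,53,56,0.995841,0.996063,0.999955
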