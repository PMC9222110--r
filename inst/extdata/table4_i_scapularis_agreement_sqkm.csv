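# I. scapularis: agreement between the standard-survey and convenience-sample
# consensus (0-5) maps, areas in sq km. Rows are the convenience score, columns
# the standard score; TOTAL row/column and grand total are the printed marginals.
convenience,s0,s1,s2,s3,s4,s5,TOTAL
0,29944.83,10627.14,6931.97,5068.29,4267.06,4264.80,61104.09
1,8927.07,4404.14,2854.61,1456.21,1716.07,2082.93,21441.03
2,7788.58,3826.18,2267.14,1522.36,1583.34,2166.29,19153.89
3,6195.48,4259.18,2184.84,1165.39,1372.35,2038.91,17216.15
4,2634.33,2888.80,1771.81,1140.65,1385.46,1481.51,11302.56
5,2522.66,3536.64,2909.03,2826.40,2954.81,1787.36,16536.90
TOTAL,58012.95,29542.08,18919.40,13179.30,13279.09,13821.80,146754.62
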