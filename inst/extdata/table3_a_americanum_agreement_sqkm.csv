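# A. americanum: agreement between the standard-survey and convenience-sample
# consensus (0-5) maps, areas in sq km. Rows are the convenience score, columns
# the standard score; TOTAL row/column and grand total are the printed marginals.
# The published cell (convenience 0, standard 1) prints as 1339.649, which is
# inconsistent with the table's own printed marginals (row, column and grand
# totals each off by exactly 12,056.84, a decimal-point shift). The value below,
# 13396.49, restores every printed marginal exactly and is the one the published
# summary kappa reproduces.
convenience,s0,s1,s2,s3,s4,s5,TOTAL
0,33184.85,13396.49,5594.45,2437.46,2532.10,4868.60,62013.95
1,20311.57,8898.76,3606.80,1890.10,2451.88,3078.75,40237.86
2,6249.33,3184.98,1488.14,1010.98,1517.70,1862.10,15313.23
3,4534.92,2758.37,1235.27,978.22,1232.57,1455.91,12195.26
4,2350.61,1608.98,1028.64,748.37,907.00,935.63,7579.23
5,1688.32,1277.32,1111.63,1644.53,1743.12,1950.17,9415.09
TOTAL,68319.60,31124.90,14064.93,8709.66,10384.37,14151.16,146754.62
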