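position,rb_N,fe_N,printed_rel_diff_pct,thigh_ma_N,legfoot_ma_N,spring_N
1,765,873,14,26,22,13
2,1498,1566,4.5,15,43,18
3,998,1054,5.6,12,7,20
4,2077,2095,0.8,16,18,34
5,586,678,15.7,17,32,10
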