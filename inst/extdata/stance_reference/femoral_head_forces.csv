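position,kind,fx,fy,fz,printed_N
1,reaction,432,-747,130,873
1,springs,-11,-5,-2,13
2,reaction,364,-1477,370,1566
2,springs,1,-3,17,18
3,reaction,45,-1017,272,1054
3,springs,-16,-3,11,20
4,reaction,-580,-1935,552,2095
4,springs,-27,2,22,34
5,reaction,-176,-530,384,678
5,springs,-6,2,7,10
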